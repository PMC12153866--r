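test_that("a single substitution increments exactly its four context cells", {
  ref <- make_micro_reference("AACGTTCA")  # pos 3 = C in window A-C-G
  muts <- tibble::tibble(sample_id = "s1", chrom = "chrT", pos = 3L,
                         ref = "C", alt = "T")
  fx <- context_features(muts, ref)
  row <- as.numeric(fx[1, -1])
  names(row) <- names(fx)[-1]
  expect_equal(sum(row), 4)
  expect_equal(unname(row["A[C>T]G"]), 1)
  expect_equal(unname(row["A[C>T]"]), 1)
  expect_equal(unname(row["[C>T]G"]), 1)
  expect_equal(unname(row["C>T"]), 1)
})

test_that("empty catalogs give all-zero rows and 150 columns always", {
  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character())
  fx <- context_features(empty, fix_ref, samples = c("a", "b"))
  expect_equal(dim(fx), c(2L, 151L))
  expect_true(all(fx[-1] == 0))
  expect_equal(names(fix_features)[-1], context_feature_names())
})

test_that("context row-sum identities hold on simulated cohorts", {
  tri <- rowSums(as.matrix(fix_features[sbs96_contexts()]))
  mono <- rowSums(as.matrix(fix_features[mono_classes()]))
  di <- di48_contexts()
  d5 <- rowSums(as.matrix(fix_features[di[1:24]]))
  d3 <- rowSums(as.matrix(fix_features[di[25:48]]))
  expect_equal(tri, mono)
  expect_equal(d5, mono)
  expect_equal(d3, mono)
  expect_true(all(as.matrix(fix_features[-1]) >= 0))
})

test_that("terminal and ambiguous-window mutations are skipped and counted", {
  ref <- make_micro_reference("AACGTTCA")
  muts <- tibble::tibble(sample_id = "s1", chrom = "chrT",
                         pos = c(1L, 8L, 3L),
                         ref = c("A", "A", "C"), alt = c("T", "T", "T"))
  fx <- context_features(muts, ref)
  expect_equal(sum(fx[1, mono_classes()]), 1)  # only the interior one
  skips <- attr(fx, "skips")
  expect_equal(nrow(skips), 2L)
  expect_true(all(skips$reason == "chromosome_terminus"))
})

test_that("reference mismatches are fatal and name the record", {
  ref <- make_micro_reference("AACGTTCA")
  muts <- tibble::tibble(sample_id = "s1", chrom = "chrT", pos = 3L,
                         ref = "G", alt = "T")
  expect_error(context_features(muts, ref), "mismatch.*chrT:3")
})

test_that("megabase bins ignore chromosome borders and conserve counts", {
  lens <- c(chr1 = 1500000L, chr2 = 1000000L)
  fx <- bin_counts(tibble::tibble(sample_id = "s", chrom = "chr1",
                                  pos = 1L, ref = "C", alt = "T"), lens)
  expect_equal(ncol(fx) - 1L, 3L)  # ceiling(2.5e6 / 1e6)

  # boundary: chr1 pos 1,000,001 has offset 1e6 -> second bin;
  # chr2 pos 1 has offset 1.5e6 -> still the second bin (borders ignored)
  muts <- tibble::tibble(sample_id = "s",
                         chrom = c("chr1", "chr1", "chr2", "chr2"),
                         pos = c(1000000L, 1000001L, 1L, 600001L),
                         ref = "C", alt = "T")
  bc <- bin_counts(muts, lens)
  expect_equal(as.numeric(bc[1, -1]), c(1, 2, 1))
  expect_equal(sum(bc[1, -1]), nrow(muts))
  expect_error(bin_counts(tibble::tibble(sample_id = "s", chrom = "chr2",
                                         pos = 1000001L, ref = "C",
                                         alt = "T"), lens),
               "beyond chromosome length")
})

test_that("per-sample bin totals equal retained mutation counts", {
  bc <- bin_counts(fix_cohort$mutations, fix_ref$lengths, bin_size = 5e4,
                   samples = fix_cohort$labels$sample_id)
  per_sample <- table(fix_cohort$mutations$sample_id)
  tot <- rowSums(as.matrix(bc[-1]))
  expect_equal(unname(tot[match(names(per_sample), bc$sample_id)]),
               unname(as.numeric(per_sample)))
})

test_that("gene counts honor overlaps and intergenic sites", {
  genes <- tibble::tibble(gene = c("g1", "g2"), chrom = "chrT",
                          start = c(0L, 3L), end = c(5L, 8L))
  muts <- tibble::tibble(sample_id = "s",
                         pos = c(4L, 2L, 9L), chrom = "chrT",
                         ref = "C", alt = "T")
  gcnt <- gene_counts(muts, genes)
  expect_equal(gcnt$g1, 2L)  # pos 4 (overlap) + pos 2
  expect_equal(gcnt$g2, 1L)  # pos 4 only
  gcnt2 <- gene_counts(muts[3, ], genes)
  expect_true(all(gcnt2[-1] == 0))
})

test_that("region filtering is a partition: WES and WIIS split WGS", {
  m <- fix_cohort$mutations
  wgs <- filter_regions(m, fix_ref$regions, "WGS")
  wes <- filter_regions(m, fix_ref$regions, "WES")
  wiis <- filter_regions(m, fix_ref$regions, "WIIS")
  expect_identical(wgs, m)
  expect_equal(nrow(wes) + nrow(wiis), nrow(m))
  key <- function(d) paste(d$sample_id, d$chrom, d$pos)
  expect_length(intersect(key(wes), key(wiis)), 0L)
  expect_setequal(c(key(wes), key(wiis)), key(m))
  lab <- annotate_regions(wes, fix_ref$regions)
  expect_true(all(lab == "exon"))
  expect_false(any(annotate_regions(wiis, fix_ref$regions) == "exon"))
})

test_that("unannotated positions fail under WES/WIIS", {
  reg <- tibble::tibble(chrom = "chrT", start = 0L, end = 4L,
                        label = "exon")  # covers only half the genome
  muts <- tibble::tibble(sample_id = "s", chrom = "chrT", pos = 6L,
                         ref = "T", alt = "A")
  expect_error(filter_regions(muts, reg, "WES"), "unannotated")
})

test_that("features from written-then-reread files equal in-memory features", {
  dir <- withr::local_tempdir()
  write_reference(fix_ref, file.path(dir, "ref"))
  write_cohort(fix_cohort, dir)
  ref2 <- read_reference(file.path(dir, "ref", "reference.fa"),
                         regions_bed = file.path(dir, "ref", "regions.bed"),
                         genes_bed = file.path(dir, "ref", "genes.bed"))
  expect_equal(ref2$sequences, fix_ref$sequences)
  expect_equal(ref2$regions$end, fix_ref$regions$end)
  files <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                      full.names = TRUE)
  muts2 <- read_vcf_mutations(files)
  fx2 <- context_features(muts2, ref2, samples = fix_cohort$labels$sample_id)
  expect_equal(fx2, fix_features, ignore_attr = TRUE)
  labels2 <- readr::read_tsv(file.path(dir, "labels.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  expect_equal(labels2$sample_id, fix_cohort$labels$sample_id)
})

test_that("multi-allelic VCF rows are split and non-SNVs dropped", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "x.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t10\t.\tC\tT,G\t.\tPASS\t.",
               "chr1\t20\t.\tCA\tC\t.\tPASS\t.",
               "chr1\t30\t.\tT\t<DEL>\t.\tPASS\t."), vcf)
  muts <- read_vcf_mutations(vcf)
  expect_equal(nrow(muts), 2L)
  expect_equal(muts$alt, c("T", "G"))
  expect_equal(muts$sample_id, c("x", "x"))
})

test_that("signature catalogs roundtrip through TSV with validation", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sigs.tsv")
  write_signature_catalog(fix_sigs, path)
  back <- read_signature_catalog(path)
  expect_equal(back, fix_sigs)
  bad <- fix_sigs
  bad$sig01 <- bad$sig01 * 2
  expect_error(validate_signature_catalog(bad), "unit-sum")
})
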