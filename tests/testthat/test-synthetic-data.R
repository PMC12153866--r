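test_that("region annotation partitions the genome exactly", {
  reg <- fix_ref$regions
  for (ch in fix_ref$chrom_names) {
    rc <- dplyr::arrange(reg[reg$chrom == ch, ], start)
    expect_equal(rc$start[1], 0L)
    expect_equal(rc$end[nrow(rc)], unname(fix_ref$lengths[ch]))
    # consecutive intervals abut: no gap, no overlap
    expect_equal(rc$start[-1], rc$end[-nrow(rc)])
  }
  expect_equal(sum(reg$end - reg$start), sum(fix_ref$lengths))
  # gene intervals lie within chromosome bounds
  expect_true(all(fix_ref$genes$start >= 0 &
                    fix_ref$genes$end <= fix_ref$lengths[fix_ref$genes$chrom]))
  # sequences contain only ACGT
  expect_false(grepl("[^ACGT]", paste(fix_ref$sequences, collapse = "")))
})

test_that("toy reference is deterministic and validates its inputs", {
  a <- make_toy_reference(c(5000, 3000), exon_fraction = 0.05,
                          gene_count = 2, seed = 42)
  b <- make_toy_reference(c(5000, 3000), exon_fraction = 0.05,
                          gene_count = 2, seed = 42)
  expect_identical(a, b)
  expect_error(make_toy_reference(c(500), seed = 1), ">= 1000")
  expect_error(make_toy_reference(c(5000), exon_fraction = 1.2, seed = 1),
               "exon_fraction")
  expect_error(make_toy_reference(c(5000), exon_fraction = 0.1,
                                  gene_count = 0, seed = 1), "gene_count")
})

test_that("exon fraction is realized within tolerance", {
  ref <- make_toy_reference(c(1000000), exon_fraction = 0.02,
                            gene_count = 5, seed = 7)
  exon <- with(ref$regions[ref$regions$label == "exon", ], sum(end - start))
  expect_gt(exon / 1e6, 0.02 - 0.005)
  expect_lt(exon / 1e6, 0.02 + 0.005)
})

test_that("a one-hot mixture emits only its trinucleotide class", {
  onehot <- tibble::tibble(context = sbs96_contexts(),
                           pure = as.numeric(sbs96_contexts() == "A[C>T]G"))
  cfg <- cohort_config(list(X = c(pure = 1)), c(X = 3L),
                       burden_median = 100, burden_sigma = 0.1, seed = 5)
  ch <- simulate_cohort(fix_ref, onehot, cfg)
  expect_gt(nrow(ch$mutations), 0)
  w <- infosig:::.reference_window(fix_ref, ch$mutations$chrom,
                                   ch$mutations$pos)
  got <- collapse_substitution(ch$mutations$ref, ch$mutations$alt,
                               w$up, w$down)
  expect_true(all(got$tri == "A[C>T]G"))
})

test_that("labels bookkeeping matches samples_per_class", {
  cfg <- cohort_config(list(X = c(sig01 = 1), Y = c(sig02 = 1)),
                       c(X = 3L, Y = 7L), burden_median = 20, seed = 2)
  ch <- simulate_cohort(fix_ref, fix_sigs, cfg)
  expect_equal(nrow(ch$labels), 10L)
  expect_equal(sort(as.integer(table(ch$labels$cancer_type))), c(3L, 7L))
  expect_true(all(c("sample_id", "cancer_type", "primary_site", "sex",
                    "age_group") %in% names(ch$labels)))
})

test_that("every emitted mutation matches the reference base", {
  w <- infosig:::.reference_window(fix_ref, fix_cohort$mutations$chrom,
                                   fix_cohort$mutations$pos)
  expect_true(all(w$ref == fix_cohort$mutations$ref))
  # interior sites only, unique within sample
  expect_true(all(fix_cohort$mutations$pos > 1))
  expect_true(all(fix_cohort$mutations$pos <
                    fix_ref$lengths[fix_cohort$mutations$chrom]))
  dup <- duplicated(fix_cohort$mutations[c("sample_id", "chrom", "pos")])
  expect_false(any(dup))
})

test_that("identical seeds reproduce identical cohorts", {
  cfg <- cohort_config(fix_class_defs[1:2],
                       stats::setNames(c(2L, 2L), LETTERS[1:2]),
                       burden_median = 50, seed = 99)
  a <- simulate_cohort(fix_ref, fix_sigs, cfg)
  b <- simulate_cohort(fix_ref, fix_sigs, cfg)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$labels, b$labels)
})

test_that("empirical class frequencies converge to the mixture profile", {
  # 100k draws on a 2.5 Mb genome (~78k sites per collapsed trinucleotide,
  # so within-sample uniqueness barely truncates anything).
  big_ref <- make_toy_reference(c(1500000, 1000000), exon_fraction = 0.02,
                                gene_count = 4, seed = 21)
  mix <- c(sig01 = 0.5, sig02 = 0.5)
  cfg <- cohort_config(list(Z = mix), c(Z = 1L),
                       burden_median = 1e5, burden_sigma = 1e-6, seed = 22)
  ch <- simulate_cohort(big_ref, fix_sigs, cfg)
  expect_gt(nrow(ch$mutations), 9e4)
  fx <- context_features(ch$mutations, big_ref)
  emp <- as.numeric(fx[1, sbs96_contexts()])
  emp <- emp / sum(emp)
  truth <- as.matrix(fix_sigs[c("sig01", "sig02")]) %*% c(0.5, 0.5)
  expect_lt(sum(abs(emp - truth)), 0.05)
})

test_that("unknown signatures and missing contexts fail loudly", {
  cfg <- cohort_config(list(X = c(nosuch = 1)), c(X = 1L), seed = 1)
  expect_error(simulate_cohort(fix_ref, fix_sigs, cfg), "unknown signature")
  tiny <- make_micro_reference("ACACACAC")  # no site for most contexts
  onehot <- tibble::tibble(context = sbs96_contexts(),
                           pure = as.numeric(sbs96_contexts() == "T[T>G]T"))
  cfg2 <- cohort_config(list(X = c(pure = 1)), c(X = 1L),
                        burden_median = 5, burden_sigma = 0.01, seed = 1)
  expect_error(simulate_cohort(tiny, onehot, cfg2), "T\\[T>G\\]T")
})

test_that("driver hotspot planting scales one gene's counts in one class", {
  cfg <- cohort_config(fix_class_defs[1:2],
                       stats::setNames(c(50L, 50L), LETTERS[1:2]),
                       burden_median = 200, burden_sigma = 0.2, seed = 31)
  ch <- simulate_cohort(fix_ref, fix_sigs, cfg)

  expect_identical(plant_driver_hotspots(ch, fix_ref, "gene01", "A", 1,
                                         seed = 1), ch)
  expect_identical(
    plant_driver_hotspots(ch, fix_ref, "gene01", character(0), 10, seed = 1),
    ch)
  expect_error(plant_driver_hotspots(ch, fix_ref, "nogene", "A", 2, seed = 1),
               "unknown gene")
  expect_error(plant_driver_hotspots(ch, fix_ref, "gene01", "Q", 2, seed = 1),
               "unknown class")

  before <- gene_counts(ch$mutations, fix_ref$genes,
                        samples = ch$labels$sample_id)
  planted <- plant_driver_hotspots(ch, fix_ref, "gene01", "A", 10, seed = 32)
  after <- gene_counts(planted$mutations, fix_ref$genes,
                       samples = ch$labels$sample_id)
  is_a <- ch$labels$cancer_type == "A"
  ratio <- mean(after$gene01[is_a]) / mean(before$gene01[is_a])
  expect_gt(ratio, 8)
  expect_lt(ratio, 12)
  # other class and other genes untouched
  expect_equal(after$gene01[!is_a], before$gene01[!is_a])
  expect_equal(after$gene02, before$gene02)
})
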