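#' Write a reference and cohort to standard file formats
#'
#' `write_reference()` writes the genome as FASTA plus two BED files (0-based
#' half-open): `regions.bed` with the exon/intron/intergenic partition and
#' `genes.bed` with named gene intervals. `write_cohort()` writes one minimal
#' VCF v4.2 per sample (CHROM, 1-based POS, ID ".", REF, ALT, QUAL ".",
#' FILTER "PASS", empty INFO) and a `labels.tsv` with sample metadata.
#'
#' @param reference A `toy_reference`.
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(dna, file.path(dir, "reference.fa"))
  readr::write_tsv(reference$regions, file.path(dir, "regions.bed"),
                   col_names = FALSE)
  readr::write_tsv(reference$genes[, c("chrom", "start", "end", "gene")],
                   file.path(dir, "genes.bed"), col_names = FALSE)
  invisible(dir)
}

#' @rdname write_reference
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_dir <- file.path(dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  for (sid in cohort$labels$sample_id) {
    mm <- cohort$mutations[cohort$mutations$sample_id == sid, ]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    mm$chrom, mm$pos, mm$ref, mm$alt)
    writeLines(c(header, body), file.path(vcf_dir, paste0(sid, ".vcf")))
  }
  readr::write_tsv(cohort$labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' Read mutation records from VCF files
#'
#' Reads one or more VCF v4.x files into the package's tidy mutation format.
#' Multi-allelic rows are split into one record per alternate allele;
#' non-SNV alleles (indels, symbolic alleles) are dropped. The sample id of
#' each record is the file's base name unless `sample_ids` is given.
#'
#' @param files Character vector of VCF paths (possibly a whole directory via
#'   `list.files(..., pattern = "\\\\.vcf$", full.names = TRUE)`).
#' @param sample_ids Optional character vector, one id per file.
#' @return Mutation tibble (`sample_id`, `chrom`, `pos`, `ref`, `alt`).
#' @export
read_vcf_mutations <- function(files, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.vcf(\\.gz)?$", "", basename(files))
  }
  stopifnot(length(sample_ids) == length(files))
  out <- purrr::map2(files, sample_ids, function(f, sid) {
    v <- vcfR::read.vcfR(f, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    if (nrow(fix) == 0L) {
      return(tibble::tibble(sample_id = character(), chrom = character(),
                            pos = integer(), ref = character(),
                            alt = character()))
    }
    alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                     fixed = TRUE)
    n_alt <- lengths(alts)
    tb <- tibble::tibble(
      sample_id = sid,
      chrom = rep(fix[, "CHROM"], n_alt),
      pos = as.integer(rep(fix[, "POS"], n_alt)),
      ref = rep(fix[, "REF"], n_alt),
      alt = unlist(alts))
    dplyr::filter(tb, .data$ref %in% .bases, .data$alt %in% .bases)
  })
  dplyr::bind_rows(out)
}

#' Read a reference genome written by [write_reference()]
#'
#' @param fasta Path to the FASTA file.
#' @param regions_bed,genes_bed Paths to the region and gene BED files
#'   (0-based half-open; genes carry the name in column 4).
#' @return A `toy_reference`.
#' @export
read_reference <- function(fasta, regions_bed = NULL, genes_bed = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta)
  sequences <- as.character(dna)
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  lengths <- stats::setNames(as.integer(nchar(sequences)), names(sequences))
  regions <- if (!is.null(regions_bed)) {
    readr::read_tsv(regions_bed, col_names = c("chrom", "start", "end",
                                               "label"),
                    col_types = "ciic", progress = FALSE)
  } else tibble::tibble(chrom = character(), start = integer(),
                        end = integer(), label = character())
  genes <- if (!is.null(genes_bed)) {
    readr::read_tsv(genes_bed, col_names = c("chrom", "start", "end", "gene"),
                    col_types = "ciic", progress = FALSE)[,
                      c("gene", "chrom", "start", "end")]
  } else tibble::tibble(gene = character(), chrom = character(),
                        start = integer(), end = integer())
  structure(list(chrom_names = names(sequences), lengths = lengths,
                 sequences = sequences, regions = regions, genes = genes),
            class = "toy_reference")
}

#' Write and read a signature catalog as TSV
#'
#' The catalog format is 96 rows (canonical trinucleotide labels in a
#' `context` column) by one numeric column per signature; columns must sum
#' to 1 within 1e-6.
#'
#' @param signatures Catalog tibble.
#' @param path TSV path.
#' @return `read_signature_catalog()` returns the validated catalog tibble.
#' @export
write_signature_catalog <- function(signatures, path) {
  readr::write_tsv(signatures, path)
  invisible(path)
}

#' @rdname write_signature_catalog
#' @export
read_signature_catalog <- function(path) {
  sig <- readr::read_tsv(path, col_types = readr::cols(
    context = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  validate_signature_catalog(sig)
}

#' @rdname write_signature_catalog
#' @export
validate_signature_catalog <- function(signatures) {
  if (!"context" %in% names(signatures)) {
    stop("signature catalog needs a 'context' column")
  }
  if (!setequal(signatures$context, sbs96_contexts())) {
    stop("signature catalog must hold exactly the 96 canonical contexts")
  }
  sums <- colSums(signatures[setdiff(names(signatures), "context")])
  bad <- names(sums)[abs(sums - 1) > 1e-6]
  if (length(bad)) {
    stop("signature column(s) not unit-sum: ", paste(bad, collapse = ", "))
  }
  signatures[match(sbs96_contexts(), signatures$context), ]
}
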