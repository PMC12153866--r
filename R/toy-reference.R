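#' Generate a toy reference genome with exon/intron/intergenic structure
#'
#' Builds a random genome over A/C/G/T with a region annotation that
#' partitions every base into `exon`, `intron` or `intergenic`, plus named
#' gene intervals. Genes are laid out as exon-intron-exon blocks, evenly
#' spaced along the genome, and sized so the exonic fraction matches
#' `exon_fraction`. All intervals are 0-based half-open; this convention is
#' used for every interval in the package (VCF positions stay 1-based).
#'
#' @param chrom_lengths Integer vector of chromosome lengths (each >= 1000),
#'   optionally named; unnamed chromosomes are called `chr1`, `chr2`, ...
#' @param exon_fraction Fraction of the genome annotated as exon, in (0, 1).
#' @param gene_count Number of named gene intervals to emit.
#' @param seed Integer seed; the same seed reproduces the reference exactly.
#' @return A `toy_reference` object: a list with `chrom_names`, `lengths`,
#'   `sequences` (named character vector), `regions` (tibble `chrom`, `start`,
#'   `end`, `label`) and `genes` (tibble `gene`, `chrom`, `start`, `end`).
#' @export
#' @examples
#' ref <- make_toy_reference(c(20000, 10000), exon_fraction = 0.1,
#'                           gene_count = 4, seed = 1)
#' ref
make_toy_reference <- function(chrom_lengths, exon_fraction = 0.02,
                               gene_count = 10L, seed = 1L) {
  chrom_lengths <- as.integer(chrom_lengths)
  if (any(chrom_lengths < 1000L)) {
    stop("make_toy_reference(): each chromosome length must be >= 1000")
  }
  if (!(exon_fraction > 0 && exon_fraction < 1)) {
    stop("make_toy_reference(): exon_fraction must lie in (0, 1)")
  }
  gene_count <- as.integer(gene_count)
  if (gene_count < 1L) stop("make_toy_reference(): gene_count must be >= 1")
  nms <- names(chrom_lengths)
  if (is.null(nms)) nms <- paste0("chr", seq_along(chrom_lengths))
  total <- sum(chrom_lengths)

  # Gene geometry: exon-intron-exon with intron twice the exon share, so a
  # gene occupies 3x its exon bases. Cap the footprint at 60% of the genome.
  exon_per_gene <- floor(exon_fraction * total / gene_count)
  if (exon_per_gene < 10L) {
    stop("make_toy_reference(): exon_fraction * genome too small for ",
         gene_count, " genes")
  }
  gene_len <- 3L * exon_per_gene
  if (gene_len * gene_count > 0.6 * total) {
    stop("make_toy_reference(): genes would cover > 60% of the genome; ",
         "reduce exon_fraction or gene_count")
  }

  withr::local_seed(seed)
  sequences <- vapply(chrom_lengths, function(L) {
    paste(sample(.bases, L, replace = TRUE), collapse = "")
  }, character(1))
  names(sequences) <- nms

  # Allocate genes to chromosomes proportionally to length (largest remainder).
  alloc <- floor(gene_count * chrom_lengths / total)
  rem <- gene_count - sum(alloc)
  if (rem > 0L) {
    frac <- gene_count * chrom_lengths / total - alloc
    alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] <- alloc[order(
      frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }

  genes <- list(); regions <- list(); gi <- 0L
  for (ci in seq_along(chrom_lengths)) {
    L <- chrom_lengths[ci]; g <- alloc[ci]
    if (g > 0L && (g * gene_len) > (L - 2L * g)) {
      stop("make_toy_reference(): chromosome ", nms[ci],
           " too short for its ", g, " genes")
    }
    if (g > 0L) {
      # Even slots; the gene sits at a seeded offset inside its slot.
      slot <- L %/% g
      free <- slot - gene_len
      starts <- (seq_len(g) - 1L) * slot +
        vapply(seq_len(g), function(i) sample.int(max(free, 1L), 1L) - 1L,
               integer(1))
      for (k in seq_len(g)) {
        gi <- gi + 1L
        s <- starts[k]
        e1 <- s + exon_per_gene %/% 2L          # end of first exon
        i2 <- e1 + 2L * exon_per_gene           # end of intron
        e2 <- s + gene_len                      # end of gene / second exon
        genes[[gi]] <- tibble::tibble(
          gene = sprintf("gene%02d", gi), chrom = nms[ci],
          start = s, end = e2)
        regions[[length(regions) + 1L]] <- tibble::tibble(
          chrom = nms[ci],
          start = c(s, e1, i2),
          end = c(e1, i2, e2),
          label = c("exon", "intron", "exon"))
      }
    }
  }
  genes <- dplyr::bind_rows(genes)
  regions <- dplyr::bind_rows(regions)
  regions <- dplyr::filter(regions, .data$end > .data$start)

  # Fill intergenic gaps per chromosome.
  gaps <- list()
  for (ci in seq_along(chrom_lengths)) {
    rc <- dplyr::arrange(
      dplyr::filter(regions, .data$chrom == nms[ci]), .data$start)
    bounds <- c(0L, rbind(rc$start, rc$end), chrom_lengths[ci])
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    if (any(keep)) {
      gaps[[length(gaps) + 1L]] <- tibble::tibble(
        chrom = nms[ci], start = as.integer(starts[keep]),
        end = as.integer(ends[keep]), label = "intergenic")
    }
  }
  regions <- dplyr::arrange(
    dplyr::bind_rows(regions, dplyr::bind_rows(gaps)),
    match(.data$chrom, nms), .data$start)

  structure(
    list(chrom_names = nms,
         lengths = stats::setNames(chrom_lengths, nms),
         sequences = sequences, regions = regions, genes = genes),
    class = "toy_reference")
}

#' @exportS3Method base::print
print.toy_reference <- function(x, ...) {
  cat("<toy_reference> ", length(x$chrom_names), " chromosome(s), ",
      format(sum(x$lengths), big.mark = ","), " bp, ",
      nrow(x$genes), " gene(s)\n", sep = "")
  exon <- sum(x$regions$end[x$regions$label == "exon"] -
                x$regions$start[x$regions$label == "exon"])
  cat("  exon fraction: ", signif(exon / sum(x$lengths), 3), "\n", sep = "")
  invisible(x)
}

# Per-chromosome integer base codes for a toy_reference.
.reference_codes <- function(reference) {
  lapply(reference$sequences, .seq_codes)
}

# Flanked window (up, ref, down) characters at 1-based positions.
.reference_window <- function(reference, chrom, pos) {
  seqs <- reference$sequences
  up <- substring(seqs[chrom], pos - 1L, pos - 1L)
  ref <- substring(seqs[chrom], pos, pos)
  down <- substring(seqs[chrom], pos + 1L, pos + 1L)
  list(up = up, ref = ref, down = down)
}
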