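#' Filter mutations by genomic region class
#'
#' Restricts a mutation catalog to the regions a study design uses: `WGS`
#' keeps everything, `WES` keeps exon-annotated sites only, `WIIS` keeps
#' intronic and intergenic sites. The annotation must partition the genome;
#' any position it does not cover is an error.
#'
#' @param mutations Tibble with `sample_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param regions Region annotation tibble (`chrom`, `start`, `end`, `label`
#'   with 0-based half-open intervals), e.g. `reference$regions`.
#' @param mode One of `"WGS"`, `"WES"`, `"WIIS"`.
#' @return The filtered mutation tibble.
#' @export
filter_regions <- function(mutations, regions, mode = c("WGS", "WES", "WIIS")) {
  mode <- match.arg(mode)
  if (mode == "WGS") return(mutations)
  lab <- annotate_regions(mutations, regions)
  keep <- if (mode == "WES") lab == "exon" else lab %in% c("intron", "intergenic")
  mutations[keep, , drop = FALSE]
}

#' @rdname filter_regions
#' @return `annotate_regions()` returns the region label of every mutation.
#' @export
annotate_regions <- function(mutations, regions) {
  out <- rep(NA_character_, nrow(mutations))
  for (ch in unique(mutations$chrom)) {
    rc <- dplyr::arrange(regions[regions$chrom == ch, ], .data$start)
    sel <- which(mutations$chrom == ch)
    p0 <- mutations$pos[sel] - 1L  # 0-based
    idx <- findInterval(p0, rc$start)
    bad <- idx == 0L | p0 >= rc$end[pmax(idx, 1L)]
    if (any(bad) || nrow(rc) == 0L) {
      stop("annotate_regions(): unannotated position(s), e.g. ", ch, ":",
           mutations$pos[sel][which(bad)[1]],
           "; the region annotation must partition the genome")
    }
    out[sel] <- rc$label[idx]
  }
  out
}

#' Build the 150-column mutation-context feature matrix
#'
#' Counts each sample's mutations in the canonical 96 trinucleotide, 48
#' one-sided dinucleotide and 6 single-nucleotide substitution classes
#' (pyrimidine-collapsed). Flanks are read from the reference genome, not the
#' input records. Each usable mutation increments exactly four cells of its
#' sample's row (one per context family; the dinucleotide family has a 5' and
#' a 3' cell). Mutations at chromosome termini or with a non-ACGT base in
#' their trinucleotide window are skipped and tallied in the `skips`
#' attribute. A mutation whose stated reference base disagrees with the
#' genome is an error.
#'
#' @param mutations Mutation tibble (`sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param reference A `toy_reference` (or any list with named `sequences` and
#'   `lengths`).
#' @param samples Optional character vector fixing the row set and order
#'   (samples without mutations get all-zero rows); defaults to the samples
#'   present in `mutations`.
#' @return Tibble with `sample_id` plus the 150 canonical feature columns
#'   ([context_feature_names()]); attribute `skips` is a tibble of skipped
#'   records with a `reason` column.
#' @export
context_features <- function(mutations, reference, samples = NULL) {
  feats <- context_feature_names()
  if (is.null(samples)) samples <- unique(mutations$sample_id)
  empty <- tibble::as_tibble(
    c(list(sample_id = samples),
      stats::setNames(rep(list(rep(0L, length(samples))), length(feats)),
                      feats)))
  if (nrow(mutations) == 0L) return(structure(empty, skips = .no_skips()))

  lens <- reference$lengths
  terminal <- mutations$pos <= 1L | mutations$pos >= lens[mutations$chrom]
  inb <- mutations$pos >= 1L & mutations$pos <= lens[mutations$chrom]
  if (any(!inb)) {
    stop("context_features(): position beyond chromosome length, e.g. ",
         mutations$chrom[!inb][1], ":", mutations$pos[!inb][1])
  }
  win <- .reference_window(reference, mutations$chrom, mutations$pos)
  mism <- !terminal & win$ref != mutations$ref
  if (any(mism)) {
    ex <- utils::head(which(mism), 5L)
    stop("context_features(): reference base mismatch for record(s): ",
         paste(sprintf("%s %s:%d %s!=%s", mutations$sample_id[ex],
                       mutations$chrom[ex], mutations$pos[ex],
                       mutations$ref[ex], win$ref[ex]), collapse = "; "))
  }
  non_acgt <- !terminal &
    (!(win$up %in% .bases) | !(win$ref %in% .bases) | !(win$down %in% .bases) |
       !(mutations$alt %in% .bases))
  usable <- !terminal & !non_acgt
  skips <- dplyr::bind_rows(
    dplyr::mutate(mutations[terminal, ], reason = "chromosome_terminus"),
    dplyr::mutate(mutations[non_acgt, ], reason = "non_acgt_window"))

  mm <- mutations[usable, , drop = FALSE]
  if (nrow(mm) == 0L) return(structure(empty, skips = skips))
  ctx <- collapse_substitution(mm$ref, mm$alt, win$up[usable], win$down[usable])
  long <- tibble::tibble(
    sample_id = rep(mm$sample_id, 4L),
    feature = c(ctx$tri, ctx$di5, ctx$di3, ctx$mono))
  counts <- dplyr::count(long, .data$sample_id, .data$feature)
  wide <- tidyr::pivot_wider(counts, names_from = "feature",
                             values_from = "n", values_fill = 0L)
  out <- dplyr::left_join(empty["sample_id"], wide, by = "sample_id")
  for (f in feats) {
    if (is.null(out[[f]])) out[[f]] <- 0L
  }
  out[is.na(out)] <- 0L
  out <- out[, c("sample_id", feats)]
  structure(tibble::as_tibble(out), skips = skips)
}

.no_skips <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 reason = character())
}

#' Megabase-bin mutation counts
#'
#' Cuts the concatenated genome (chromosome borders ignored) into consecutive
#' fixed-size bins and counts each sample's mutations per bin. The global
#' offset of a mutation is the summed length of all preceding chromosomes
#' plus `pos - 1`; its bin is `floor(offset / bin_size)`. The last partial
#' bin is retained, so there are `ceiling(total length / bin_size)` bins.
#'
#' @param mutations Mutation tibble.
#' @param chrom_lengths Named integer vector of chromosome lengths in the
#'   fixed concatenation order (e.g. `reference$lengths`).
#' @param bin_size Bin width in bases (default 1 Mb).
#' @param samples Optional fixed row set, as in [context_features()].
#' @return Tibble with `sample_id` plus one `bin_###` column per bin.
#' @export
bin_counts <- function(mutations, chrom_lengths, bin_size = 1e6,
                       samples = NULL) {
  n_bins <- as.integer(ceiling(sum(chrom_lengths) / bin_size))
  bins <- sprintf("bin_%03d", seq_len(n_bins))
  if (is.null(samples)) samples <- unique(mutations$sample_id)
  offs <- c(0, cumsum(as.numeric(chrom_lengths)))
  ci <- match(mutations$chrom, names(chrom_lengths))
  if (anyNA(ci)) {
    stop("bin_counts(): unknown chromosome ", mutations$chrom[is.na(ci)][1])
  }
  if (any(mutations$pos < 1L | mutations$pos > chrom_lengths[ci])) {
    stop("bin_counts(): position beyond chromosome length")
  }
  offset <- offs[ci] + mutations$pos - 1
  bin <- floor(offset / bin_size) + 1L
  long <- tibble::tibble(sample_id = mutations$sample_id,
                         feature = bins[bin])
  .counts_to_wide(long, samples, bins)
}

#' Per-gene mutation counts
#'
#' Counts each sample's mutations inside every gene interval; a mutation
#' falling in k overlapping genes increments all k.
#'
#' @param mutations Mutation tibble.
#' @param genes Gene interval tibble (`gene`, `chrom`, `start`, `end`;
#'   0-based half-open), e.g. `reference$genes`.
#' @param samples Optional fixed row set.
#' @return Tibble with `sample_id` plus one column per gene.
#' @export
gene_counts <- function(mutations, genes, samples = NULL) {
  if (is.null(samples)) samples <- unique(mutations$sample_id)
  long <- list()
  for (ch in unique(genes$chrom)) {
    gg <- genes[genes$chrom == ch, ]
    sel <- which(mutations$chrom == ch)
    if (!length(sel)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = mutations$pos[sel], width = 1L),
      IRanges::IRanges(start = gg$start + 1L, end = gg$end))
    if (length(hits)) {
      long[[length(long) + 1L]] <- tibble::tibble(
        sample_id = mutations$sample_id[sel][S4Vectors::queryHits(hits)],
        feature = gg$gene[S4Vectors::subjectHits(hits)])
    }
  }
  long <- if (length(long)) dplyr::bind_rows(long) else
    tibble::tibble(sample_id = character(), feature = character())
  .counts_to_wide(long, samples, genes$gene)
}

# Long (sample_id, feature) occurrences -> wide count tibble with fixed
# column order and all-zero rows for absent samples.
.counts_to_wide <- function(long, samples, features) {
  empty <- tibble::as_tibble(
    c(list(sample_id = samples),
      stats::setNames(rep(list(rep(0L, length(samples))), length(features)),
                      features)))
  if (nrow(long) == 0L) return(empty)
  counts <- dplyr::count(long, .data$sample_id, .data$feature)
  wide <- tidyr::pivot_wider(counts, names_from = "feature",
                             values_from = "n", values_fill = 0L)
  out <- dplyr::left_join(empty["sample_id"], wide, by = "sample_id")
  for (f in features) if (is.null(out[[f]])) out[[f]] <- 0L
  out[is.na(out)] <- 0L
  tibble::as_tibble(out[, c("sample_id", features)])
}
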