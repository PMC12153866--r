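#' Random ground-truth mutational signature profiles
#'
#' Draws signature profiles over the 96 trinucleotide classes. Each signature
#' concentrates `1 - noise` of its mass uniformly on `n_dominant` randomly
#' chosen contexts (disjoint across signatures while contexts remain) and
#' spreads the remaining `noise` uniformly over all 96, mimicking the peaked
#' shape of single-base-substitution signatures.
#'
#' @param n Number of signatures.
#' @param n_dominant Dominant contexts per signature.
#' @param noise Mass spread uniformly over all contexts, in \[0, 1).
#' @param seed Integer seed.
#' @return A signature catalog: tibble with a `context` column (the 96
#'   canonical labels) and one unit-sum numeric column per signature.
#' @export
#' @examples
#' sigs <- make_signature_set(3, seed = 1)
#' colSums(sigs[-1])
make_signature_set <- function(n, n_dominant = 3L, noise = 0.1, seed = 1L) {
  stopifnot(n >= 1, n_dominant >= 1, noise >= 0, noise < 1)
  withr::local_seed(seed)
  ctx <- sbs96_contexts()
  pool <- sample.int(96L)
  out <- tibble::tibble(context = ctx)
  for (i in seq_len(n)) {
    take <- seq_len(n_dominant) + (i - 1L) * n_dominant
    idx <- if (max(take) <= 96L) pool[take] else sample.int(96L, n_dominant)
    p <- rep(noise / 96, 96)
    p[idx] <- p[idx] + (1 - noise) / n_dominant
    out[[sprintf("sig%02d", i)]] <- p
  }
  out
}

#' Dominant contexts of a signature catalog
#'
#' @param signatures Signature catalog tibble (`context` + profile columns).
#' @param n Number of top contexts per signature.
#' @return Tibble `signature`, `context`, `weight`.
#' @export
dominant_contexts <- function(signatures, n = 3L) {
  long <- tidyr::pivot_longer(signatures, -"context",
                              names_to = "signature", values_to = "weight")
  dplyr::ungroup(dplyr::slice_max(
    dplyr::group_by(long, .data$signature), .data$weight, n = n,
    with_ties = FALSE))
}

#' Cohort simulation configuration
#'
#' Describes a labeled multi-class cohort: per class a convex mixture of
#' signature profiles, a (possibly imbalanced) number of samples, and a
#' log-normal per-sample mutation-burden law given by its median and
#' log-scale dispersion.
#'
#' @param class_defs Named list; one element per cancer-type label, each a
#'   named numeric vector of signature mixture weights (non-negative, sum 1;
#'   names must be catalog columns).
#' @param samples_per_class Named integer vector (same names as `class_defs`),
#'   each >= 1.
#' @param burden_median Median of the per-sample total mutation count.
#' @param burden_sigma Log-scale standard deviation of the burden law.
#' @param primary_sites Optional named character vector mapping class to
#'   primary site; defaults to one site per class.
#' @param confound_metadata If `TRUE`, sex and age-group frequencies differ by
#'   class (for confounder-robustness experiments); by default metadata are
#'   drawn independently of class.
#' @param seed Integer seed used by [simulate_cohort()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(class_defs, samples_per_class,
                          burden_median = 500, burden_sigma = 0.5,
                          primary_sites = NULL, confound_metadata = FALSE,
                          seed = 1L) {
  stopifnot(is.list(class_defs), length(class_defs) >= 1)
  if (!setequal(names(class_defs), names(samples_per_class))) {
    stop("cohort_config(): class_defs and samples_per_class name mismatch")
  }
  for (cl in names(class_defs)) {
    w <- class_defs[[cl]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("cohort_config(): mixture weights for class ", cl,
           " must be convex (non-negative, sum 1)")
    }
  }
  if (any(samples_per_class < 1L)) {
    stop("cohort_config(): samples_per_class must be >= 1")
  }
  if (is.null(primary_sites)) {
    primary_sites <- stats::setNames(
      paste0("site_", names(class_defs)), names(class_defs))
  }
  structure(list(class_defs = class_defs,
                 samples_per_class = samples_per_class,
                 burden_median = burden_median, burden_sigma = burden_sigma,
                 primary_sites = primary_sites,
                 confound_metadata = isTRUE(confound_metadata),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Index of valid mutation sites by collapsed reference trinucleotide (32 keys).
# Global 1-based coordinates over concatenated chromosomes; chromosome ends
# (no flank) are never indexed.
.site_index <- function(reference) {
  codes <- .reference_codes(reference)
  offs <- c(0L, cumsum(reference$lengths))[seq_along(codes)]
  keys <- integer(0); gpos <- integer(0)
  for (ci in seq_along(codes)) {
    k <- .position_keys(codes[[ci]])
    p <- seq_along(k) + 1L  # interior 1-based positions
    keep <- !is.na(k)
    keys <- c(keys, k[keep])
    gpos <- c(gpos, p[keep] + offs[ci])
  }
  split(gpos, factor(keys, levels = 1:32))
}

# Map a global 1-based position back to (chrom, pos).
.global_to_local <- function(reference, gpos) {
  offs <- c(0L, cumsum(reference$lengths))
  # A global position belongs to the last chromosome whose cumulative end is
  # strictly below it.
  ci <- findInterval(gpos, offs[-1L], left.open = TRUE) + 1L
  list(chrom = reference$chrom_names[ci],
       pos = as.integer(gpos - offs[ci]),
       chrom_idx = ci)
}

#' Simulate a labeled synthetic mutation cohort
#'
#' For every sample, a total burden N is drawn from the log-normal burden law,
#' N trinucleotide mutation classes are drawn from the sample's class mixture
#' profile, and each mutation is placed uniformly at random on a genomic site
#' whose collapsed reference trinucleotide matches the class (both strands
#' considered under pyrimidine collapsing). When the matching site carries the
#' purine strand, the emitted ref/alt are the complements of the class's
#' pyrimidine-strand bases. Sites are unique within a sample; chromosome
#' termini are never mutated.
#'
#' @param reference A [make_toy_reference()] object.
#' @param signatures Signature catalog tibble (`context` column + one
#'   unit-sum profile column per signature).
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list: `mutations` (tibble `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`), `labels` (tibble `sample_id`,
#'   `cancer_type`, `primary_site`, `sex`, `age_group`) and `config`.
#' @export
#' @examples
#' ref <- make_toy_reference(c(50000), exon_fraction = 0.1, gene_count = 2,
#'                           seed = 1)
#' sigs <- make_signature_set(2, seed = 1)
#' cfg <- cohort_config(
#'   list(A = c(sig01 = 1), B = c(sig02 = 1)),
#'   samples_per_class = c(A = 3, B = 3), burden_median = 50, seed = 7)
#' ch <- simulate_cohort(ref, sigs, cfg)
#' dplyr::count(ch$labels, cancer_type)
simulate_cohort <- function(reference, signatures, config) {
  stopifnot(inherits(reference, "toy_reference"),
            inherits(config, "cohort_config"))
  profiles <- .class_profiles(signatures, config)
  tab <- .sbs96_table()
  index <- .site_index(reference)
  withr::local_seed(config$seed)

  classes <- names(config$class_defs)
  muts <- list(); labels <- list(); sid <- 0L
  for (cl in classes) {
    p <- profiles[[cl]]
    for (i in seq_len(config$samples_per_class[[cl]])) {
      sid <- sid + 1L
      sample_id <- sprintf("%s_%03d", cl, i)
      n <- max(0L, round(stats::rlnorm(1, log(config$burden_median),
                                       config$burden_sigma)))
      if (n > 0L) {
        counts <- as.integer(stats::rmultinom(1, n, p))
        drawn <- .draw_sites(counts, tab, index)
        if (length(drawn$gpos)) {
          loc <- .global_to_local(reference, drawn$gpos)
          codes <- substring(reference$sequences[loc$chrom], loc$pos, loc$pos)
          cls <- drawn$class
          flip <- !(codes %in% c("C", "T"))
          ref_b <- ifelse(flip, .comp[tab$mono_ref_chr[cls]],
                          tab$mono_ref_chr[cls])
          alt_b <- ifelse(flip, .comp[tab$mono_alt_chr[cls]],
                          tab$mono_alt_chr[cls])
          muts[[sid]] <- tibble::tibble(
            sample_id = sample_id, chrom = loc$chrom, pos = loc$pos,
            ref = unname(ref_b), alt = unname(alt_b))
        }
      }
      labels[[sid]] <- tibble::tibble(
        sample_id = sample_id, cancer_type = cl,
        primary_site = unname(config$primary_sites[[cl]]))
    }
  }
  labels <- dplyr::bind_rows(labels)
  labels <- .draw_metadata(labels, config)
  mutations <- if (length(muts)) {
    dplyr::arrange(dplyr::bind_rows(muts), .data$sample_id,
                   match(.data$chrom, reference$chrom_names), .data$pos)
  } else {
    tibble::tibble(sample_id = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character())
  }
  structure(list(mutations = mutations, labels = labels, config = config),
            class = "synthetic_cohort")
}

# Resolve per-class 96-context profiles from the catalog and mixtures.
.class_profiles <- function(signatures, config) {
  ctx <- sbs96_contexts()
  if (!identical(signatures$context, ctx)) {
    signatures <- signatures[match(ctx, signatures$context), ]
    if (anyNA(signatures$context)) {
      stop("simulate_cohort(): signature catalog must cover all 96 contexts")
    }
  }
  lapply(config$class_defs, function(w) {
    missing <- setdiff(names(w), names(signatures))
    if (length(missing)) {
      stop("simulate_cohort(): unknown signature(s): ",
           paste(missing, collapse = ", "))
    }
    as.numeric(as.matrix(signatures[names(w)]) %*% w)
  })
}

# Draw `counts[class]` unique sites per class from the trinucleotide index;
# deduplicate positions across classes within the sample.
.draw_sites <- function(counts, tab, index) {
  cls <- integer(0); gpos <- integer(0)
  for (m in which(counts > 0L)) {
    sites <- index[[tab$key[m]]]
    k <- counts[m]
    if (length(sites) < k) {
      if (length(sites) == 0L) {
        stop("simulate_cohort(): no genomic site carries the reference ",
             "trinucleotide for context ", tab$tri[m])
      }
      k <- length(sites)
    }
    pick <- sites[sample.int(length(sites), k)]
    cls <- c(cls, rep.int(m, k))
    gpos <- c(gpos, pick)
  }
  keep <- !duplicated(gpos)
  list(class = cls[keep], gpos = gpos[keep])
}

# Sex and age-group labels; optionally class-dependent (confounded).
.draw_metadata <- function(labels, config) {
  ages <- c("(0,25]", "(25,50]", "(50,75]", "(75,100]")
  n <- nrow(labels)
  if (config$confound_metadata) {
    cls_i <- as.integer(factor(labels$cancer_type))
    p_f <- 0.2 + 0.6 * (cls_i %% 2L)
    labels$sex <- ifelse(stats::runif(n) < p_f, "female", "male")
    labels$age_group <- ages[1L + (cls_i + stats::rbinom(n, 1, 0.3)) %% 4L]
  } else {
    labels$sex <- sample(c("female", "male"), n, replace = TRUE)
    labels$age_group <- sample(ages, n, replace = TRUE,
                               prob = c(0.05, 0.25, 0.5, 0.2))
  }
  labels
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$labels), " samples, ",
      nrow(x$mutations), " mutations, ",
      length(unique(x$labels$cancer_type)), " classes\n", sep = "")
  invisible(x)
}

#' Plant extra mutations in a gene for selected classes
#'
#' Multiplies the expected per-sample mutation count of one gene for the
#' samples of the given classes: each affected sample with current count c in
#' the gene receives `Poisson((multiplier - 1) * c)` additional mutations at
#' uniformly chosen interior gene sites not already mutated in that sample
#' (alt base uniform over the three non-reference bases). Other samples are
#' untouched; `multiplier = 1` or an empty class set returns the cohort
#' unchanged.
#'
#' @param cohort A `synthetic_cohort`.
#' @param reference The `toy_reference` the cohort was simulated on.
#' @param gene Gene identifier present in `reference$genes`.
#' @param classes Character vector of cancer-type labels to affect.
#' @param multiplier Rate factor >= 1.
#' @param seed Integer seed.
#' @return The modified `synthetic_cohort`.
#' @export
plant_driver_hotspots <- function(cohort, reference, gene, classes,
                                  multiplier, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(reference, "toy_reference"))
  if (multiplier < 1) stop("plant_driver_hotspots(): multiplier must be >= 1")
  g <- dplyr::filter(reference$genes, .data$gene == !!gene)
  if (nrow(g) != 1L) stop("plant_driver_hotspots(): unknown gene ", gene)
  known <- unique(cohort$labels$cancer_type)
  bad <- setdiff(classes, known)
  if (length(bad)) {
    stop("plant_driver_hotspots(): unknown class(es): ",
         paste(bad, collapse = ", "))
  }
  if (multiplier == 1 || length(classes) == 0L) return(cohort)

  withr::local_seed(seed)
  targets <- cohort$labels$sample_id[cohort$labels$cancer_type %in% classes]
  # Interior candidate positions (1-based) inside the gene, flanks available.
  lo <- max(g$start + 1L, 2L)
  hi <- min(g$end, reference$lengths[[g$chrom]] - 1L)
  cand <- seq.int(lo, hi)
  seqs <- reference$sequences[[g$chrom]]
  extra <- list()
  for (sid in targets) {
    in_gene <- cohort$mutations$sample_id == sid &
      cohort$mutations$chrom == g$chrom &
      cohort$mutations$pos > g$start & cohort$mutations$pos <= g$end
    cnt <- sum(in_gene)
    n_extra <- stats::rpois(1, (multiplier - 1) * cnt)
    if (n_extra == 0L) next
    used <- cohort$mutations$pos[cohort$mutations$sample_id == sid &
                                   cohort$mutations$chrom == g$chrom]
    avail <- setdiff(cand, used)
    n_extra <- min(n_extra, length(avail))
    pos <- if (length(avail) == 1L) avail else
      avail[sample.int(length(avail), n_extra)]
    refb <- substring(seqs, pos, pos)
    altb <- vapply(refb, function(r) sample(setdiff(.bases, r), 1L),
                   character(1))
    extra[[length(extra) + 1L]] <- tibble::tibble(
      sample_id = sid, chrom = g$chrom, pos = as.integer(pos),
      ref = refb, alt = unname(altb))
  }
  if (length(extra)) {
    cohort$mutations <- dplyr::arrange(
      dplyr::bind_rows(cohort$mutations, dplyr::bind_rows(extra)),
      .data$sample_id, match(.data$chrom, reference$chrom_names), .data$pos)
  }
  cohort
}
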