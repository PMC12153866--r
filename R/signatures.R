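#' Build an informative mutational signature
#'
#' An informative mutational signature pairs a cancer type's mean
#' 96-context mutation frequency profile with the positive part of the
#' per-feature median normalized LRP relevance: each sample's trinucleotide
#' counts are normalized to frequencies and averaged, and each feature's
#' relevance is `max(median, 0)`. Samples with zero mutations are excluded
#' with a warning.
#'
#' @param class_features Feature tibble (`sample_id` + at least the 96
#'   trinucleotide columns) restricted to one class's samples.
#' @param class_stats Tibble from [aggregate_relevance()] (only the rows of
#'   the matching class are used if a `class` column is present).
#' @param cancer_type Label of the class; taken from `class_stats` when
#'   unique.
#' @return An `informative_signature`: tibble `context`, `frequency`,
#'   `relevance` (96 rows, frequency unit-sum, relevance >= 0) with
#'   attribute `cancer_type`.
#' @export
informative_signature <- function(class_features, class_stats,
                                  cancer_type = NULL) {
  ctx <- sbs96_contexts()
  miss <- setdiff(ctx, names(class_features))
  if (length(miss)) {
    stop("informative_signature(): missing trinucleotide column(s), e.g. ",
         miss[1])
  }
  M <- as.matrix(class_features[ctx])
  tot <- rowSums(M)
  if (any(tot == 0)) {
    warning("informative_signature(): excluding ", sum(tot == 0),
            " sample(s) with zero mutations")
    M <- M[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (!nrow(M)) stop("informative_signature(): no usable samples")
  freq <- colMeans(M / tot)

  if ("class" %in% names(class_stats)) {
    if (is.null(cancer_type)) {
      cls <- unique(class_stats$class)
      if (length(cls) != 1L) {
        stop("informative_signature(): supply cancer_type; class_stats has ",
             length(cls), " classes")
      }
      cancer_type <- cls
    }
    class_stats <- class_stats[class_stats$class == cancer_type, ]
  }
  med <- class_stats$median[match(ctx, class_stats$feature)]
  if (anyNA(med)) {
    stop("informative_signature(): class_stats lacks some trinucleotide ",
         "features")
  }
  out <- tibble::tibble(context = ctx, frequency = unname(freq),
                        relevance = pmax(med, 0))
  structure(out, class = c("informative_signature", class(out)),
            cancer_type = cancer_type %||% NA_character_)
}

#' Feature-focused distance and similarity between signatures
#'
#' The feature-focused distance between two unit-sum profiles is the summed
#' absolute difference over corresponding features divided by 2, the maximum
#' possible summed difference, mapping it to \[0, 1\].
#' `featurewise_abs_similarity()` is its complement, 1 - distance.
#'
#' @param a,b Numeric unit-sum vectors of equal length (e.g. the `frequency`
#'   column of two signatures).
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' feature_focused_distance(c(1, 0), c(0, 1)) # disjoint one-hots -> 1
feature_focused_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("feature_focused_distance(): length mismatch")
  }
  sum(abs(a - b)) / 2
}

#' @rdname feature_focused_distance
#' @export
featurewise_abs_similarity <- function(a, b) {
  1 - feature_focused_distance(a, b)
}

#' Pearson correlation with degenerate-input flagging
#'
#' Plain Pearson correlation, `cov(x, y) / (sd(x) sd(y))`; a zero-variance
#' input is undefined and returns `NA` with a warning rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_correlation(): length mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson_correlation(): zero-variance input; undefined")
    return(NA_real_)
  }
  stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
}

# Positive relevance renormalized to sum 1.
.renorm_relevance <- function(r, who = "relevance_weighted_distance()") {
  r <- pmax(r, 0)
  s <- sum(r)
  if (s == 0) stop(who, ": all-zero relevance vector")
  r / s
}

#' Relevance-weighted distance between informative signatures
#'
#' Weighted sum of absolute frequency differences, with the per-feature
#' weight the sum of the two signatures' normalized positive relevance
#' values, normalized by its maximum, the sum of the two signatures' highest
#' relevance values:
#' \deqn{D(A,B) = \frac{\sum_i (r_i^A + r_i^B)\,|f_i^A - f_i^B|}
#'   {\max_i r_i^A + \max_i r_i^B}.}
#' Each relevance vector is first renormalized to sum 1 over its positive
#' entries. The distance is symmetric and zero between identical signatures.
#'
#' @param A,B `informative_signature` objects (or tibbles with `frequency`
#'   and `relevance` columns over the same feature order).
#' @return A non-negative number (1 is the one-hot worst case).
#' @export
relevance_weighted_distance <- function(A, B) {
  rA <- .renorm_relevance(A$relevance)
  rB <- .renorm_relevance(B$relevance)
  num <- sum((rA + rB) * abs(A$frequency - B$frequency))
  num / (max(rA) + max(rB))
}

#' Fit a reference-signature combination to an informative signature
#'
#' Searches all single catalog signatures and all unordered pairs with
#' convex weights on the grid `{0, weight_step, ..., 1}` for the mixture
#' whose 96-context profile is closest to the target's frequency profile
#' under the relevance-weighted distance (weights: the target's renormalized
#' positive relevance; normalizer: twice its maximum, the one-relevance-
#' vector analog of the pairwise normalizer). The combination fits if its
#' distance is below 5% of the maximal (worst-case) distance.
#'
#' @param target An `informative_signature`.
#' @param catalog Signature catalog tibble (`context` + one unit-sum column
#'   per signature), e.g. from [read_signature_catalog()]; any dimension is
#'   accepted as long as it matches the target's feature count.
#' @param weight_step Grid step for pair weights.
#' @param fit_fraction Fitting rule: fits iff distance < `fit_fraction` *
#'   maximal distance.
#' @return A `combination_fit` list: `cancer_type`, `signatures` (1 or 2
#'   names), `weights`, `distance` (normalized to the \[0, 1\] worst case),
#'   `max_distance` (= 1 after normalization), `fits`, and the full ranked
#'   `search` tibble.
#' @export
fit_signature_combination <- function(target, catalog, weight_step = 0.05,
                                      fit_fraction = 0.05) {
  sig_names <- setdiff(names(catalog), "context")
  if (!length(sig_names)) stop("fit_signature_combination(): empty catalog")
  S <- as.matrix(catalog[sig_names])
  if (nrow(S) != nrow(target)) {
    stop("fit_signature_combination(): catalog/target dimension mismatch")
  }
  f <- target$frequency
  r <- .renorm_relevance(target$relevance, "fit_signature_combination()")
  denom <- 2 * max(r)
  score_profile <- function(M) {
    # columns of M are candidate profiles
    unname(colSums(2 * r * abs(f - M))) / denom
  }

  singles <- tibble::tibble(
    sig1 = sig_names, sig2 = NA_character_, w1 = 1,
    distance = score_profile(S))
  pairs <- NULL
  if (length(sig_names) >= 2L) {
    idx <- utils::combn(length(sig_names), 2L)
    grid <- seq(0, 1, by = weight_step)
    grid <- grid[grid > 0 & grid < 1]
    rows <- vector("list", ncol(idx))
    for (j in seq_len(ncol(idx))) {
      i1 <- idx[1, j]; i2 <- idx[2, j]
      M <- S[, i1] %o% grid + S[, i2] %o% (1 - grid)
      rows[[j]] <- tibble::tibble(
        sig1 = sig_names[i1], sig2 = sig_names[i2], w1 = grid,
        distance = score_profile(M))
    }
    pairs <- dplyr::bind_rows(rows)
  }
  search <- dplyr::arrange(dplyr::bind_rows(singles, pairs), .data$distance)
  best <- search[1, ]
  fits <- best$distance < fit_fraction * 1
  structure(list(
    cancer_type = attr(target, "cancer_type"),
    signatures = if (is.na(best$sig2)) best$sig1 else
      c(best$sig1, best$sig2),
    weights = if (is.na(best$sig2)) 1 else c(best$w1, 1 - best$w1),
    distance = best$distance, max_distance = 1, fits = fits,
    search = search), class = "combination_fit")
}

#' @exportS3Method base::print
print.combination_fit <- function(x, ...) {
  cat("<combination_fit> ", x$cancer_type %||% "?", ": ",
      paste(sprintf("%s (%.2f)", x$signatures, x$weights), collapse = " + "),
      "\n  distance ", signif(x$distance, 4),
      if (x$fits) "  [fits]" else "  [does not fit]", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_signature_combination
#' @param x A `combination_fit`.
#' @export
tidy.combination_fit <- function(x, ...) {
  tibble::tibble(cancer_type = x$cancer_type %||% NA_character_,
                 signature = x$signatures,
                 weight = x$weights,
                 distance = x$distance, fits = x$fits)
}
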