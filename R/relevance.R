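#' Layer-wise relevance propagation with the epsilon rule
#'
#' Explains individual predictions of a [fit_network()] classifier by
#' redistributing the target class's pre-softmax output backward through the
#' network. The output-layer relevance is initialized to that pre-softmax
#' value (zero for all other output units) and propagated with the
#' sign-following epsilon rule
#' \deqn{R_{i \leftarrow j} = \frac{z_{ij}}{z_j + \epsilon} R_j
#'   \ (z_j \ge 0), \qquad
#'   R_{i \leftarrow j} = \frac{z_{ij}}{z_j - \epsilon} R_j\ (z_j < 0),}
#' where \eqn{z_{ij} = a_i w_{ij}} and \eqn{z_j = \sum_i z_{ij} + b_j};
#' \eqn{R_i = \sum_j R_{i \leftarrow j}}. Rectified-linear layers propagate
#' through the traced activations; dropout is inactive. Bias relevance is
#' absorbed, not redistributed. Relevance is attributed to the standardized
#' inputs the network actually consumes.
#'
#' @param network A `trained_network`.
#' @param features Feature tibble (`sample_id` + feature columns).
#' @param target Target class per sample: `"predicted"` (default) explains
#'   each sample's predicted label; alternatively one class label recycled to
#'   all samples, or a character vector of length `nrow(features)`.
#' @param epsilon Positive stabilizer added (sign-following) to each
#'   denominator.
#' @return A relevance tibble: `sample_id`, `.target`, `.pre_softmax`, then
#'   one signed raw-relevance column per input feature. Attribute
#'   `normalized` is `FALSE`.
#' @export
lrp_epsilon <- function(network, features, target = "predicted",
                        epsilon = 1e-6) {
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("lrp_epsilon(): epsilon must be > 0")
  }
  miss <- setdiff(network$feature_names, names(features))
  if (length(miss)) {
    stop("lrp_epsilon(): missing feature column(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  X <- as.matrix(features[network$feature_names])
  storage.mode(X) <- "double"
  X <- sweep(sweep(X, 2L, network$center), 2L, network$scale, "/")
  fw <- .forward(network, X, trace = TRUE, n_hidden = network$n_hidden)
  logits <- fw$logits
  n <- nrow(X)
  if (identical(target, "predicted")) {
    ti <- max.col(.softmax(logits), ties.method = "first")
  } else {
    tgt <- rep_len(target, n)
    ti <- match(tgt, network$classes)
    if (anyNA(ti)) stop("lrp_epsilon(): unknown target class ",
                        tgt[is.na(ti)][1])
  }
  R <- matrix(0, n, ncol(logits))
  R[cbind(seq_len(n), ti)] <- logits[cbind(seq_len(n), ti)]
  pre_softmax <- logits[cbind(seq_len(n), ti)]
  for (l in rev(seq_along(network$W))) {
    A <- fw$acts[[l]]
    Z <- A %*% network$W[[l]] + rep(network$b[[l]], each = n)
    denom <- Z + ifelse(Z >= 0, epsilon, -epsilon)
    S <- R / denom
    R <- (S %*% t(network$W[[l]])) * A
  }
  out <- tibble::tibble(sample_id = features$sample_id,
                        .target = network$classes[ti],
                        .pre_softmax = pre_softmax)
  colnames(R) <- network$feature_names
  out <- dplyr::bind_cols(out, tibble::as_tibble(R))
  attr(out, "normalized") <- FALSE
  out
}

#' Normalize relevance by total absolute relevance
#'
#' Divides each sample's raw relevance by the sum of its absolute values, so
#' signed shares are comparable across predictions; signs are preserved and
#' the absolute normalized values sum to 1. Samples with all-zero raw
#' relevance are flagged (attribute `degenerate`) and their normalized values
#' set to `NA` so they drop out of aggregation.
#'
#' @param relevance A relevance tibble from [lrp_epsilon()].
#' @return The tibble with feature columns normalized; attribute
#'   `normalized` set to `TRUE`.
#' @export
normalize_relevance <- function(relevance) {
  feats <- setdiff(names(relevance),
                   c("sample_id", ".target", ".pre_softmax"))
  R <- as.matrix(relevance[feats])
  tot <- rowSums(abs(R))
  degenerate <- tot == 0
  tot[degenerate] <- NA_real_
  R <- R / tot
  relevance[feats] <- tibble::as_tibble(R)
  attr(relevance, "normalized") <- TRUE
  attr(relevance, "degenerate") <- relevance$sample_id[degenerate]
  if (any(degenerate)) {
    warning("normalize_relevance(): ", sum(degenerate),
            " sample(s) with all-zero relevance flagged")
  }
  relevance
}

#' Per-class relevance summary statistics
#'
#' Median, mean, standard deviation, minimum and maximum of the normalized
#' relevance of every feature over the samples explained as each class (the
#' target label of the relevance rows, i.e. the predicted class when
#' relevance was computed with `target = "predicted"`). The median feeds the
#' informative mutational signatures.
#'
#' @param relevance A normalized relevance tibble ([normalize_relevance()]).
#' @return Tibble `class`, `feature`, `n`, `median`, `mean`, `sd`, `min`,
#'   `max` (sd is 0 for singleton classes).
#' @export
aggregate_relevance <- function(relevance) {
  if (!isTRUE(attr(relevance, "normalized"))) {
    warning("aggregate_relevance(): relevance does not look normalized")
  }
  feats <- setdiff(names(relevance),
                   c("sample_id", ".target", ".pre_softmax"))
  long <- tidyr::pivot_longer(
    relevance[stats::complete.cases(relevance[feats]), ],
    dplyr::all_of(feats), names_to = "feature", values_to = "relevance")
  out <- dplyr::summarise(
    dplyr::group_by(long, class = .data$.target, .data$feature),
    n = dplyr::n(),
    median = stats::median(.data$relevance),
    mean = mean(.data$relevance),
    sd = if (dplyr::n() > 1L) stats::sd(.data$relevance) else 0,
    min = min(.data$relevance),
    max = max(.data$relevance),
    .groups = "drop")
  out <- dplyr::arrange(out, .data$class,
                        match(.data$feature, feats))
  out
}

#' Quantitative-LRP feature sets
#'
#' For each explained sample, walks the features in descending order of
#' absolute raw relevance, accumulating the signed relevance, and keeps the
#' shortest prefix whose cumulative sum reaches `fraction` of the pre-softmax
#' value (the initial relevance of the backward pass). Only samples with a
#' positive pre-softmax value are analyzed; if the cumulative sum never
#' reaches the threshold, all features are returned with `reached = FALSE`.
#'
#' @param relevance A raw (unnormalized) relevance tibble from
#'   [lrp_epsilon()].
#' @param fraction Fraction of the pre-softmax value to reach (default 0.8).
#' @param absolute If `TRUE`, accumulate absolute instead of signed
#'   relevance (sensitivity analysis; default `FALSE`, the signed walk).
#' @return Tibble `sample_id`, `target`, `feature`, `rank`, `relevance`,
#'   `reached`.
#' @export
quantitative_lrp_set <- function(relevance, fraction = 0.8,
                                 absolute = FALSE) {
  feats <- setdiff(names(relevance),
                   c("sample_id", ".target", ".pre_softmax"))
  keep <- relevance$.pre_softmax > 0
  if (any(!keep)) {
    warning("quantitative_lrp_set(): dropping ", sum(!keep),
            " sample(s) with non-positive pre-softmax value")
  }
  relevance <- relevance[keep, , drop = FALSE]
  R <- as.matrix(relevance[feats])
  out <- vector("list", nrow(relevance))
  for (i in seq_len(nrow(relevance))) {
    r <- R[i, ]
    ord <- order(abs(r), decreasing = TRUE)
    cum <- cumsum(if (absolute) abs(r[ord]) else r[ord])
    thr <- fraction * relevance$.pre_softmax[i]
    hit <- which(cum >= thr)
    if (length(hit)) {
      m <- hit[1]; reached <- TRUE
    } else {
      m <- length(ord); reached <- FALSE
    }
    out[[i]] <- tibble::tibble(
      sample_id = relevance$sample_id[i],
      target = relevance$.target[i],
      feature = feats[ord[seq_len(m)]],
      rank = seq_len(m),
      relevance = unname(r[ord[seq_len(m)]]),
      reached = reached)
  }
  dplyr::bind_rows(out)
}

#' Driver-gene candidates from quantitative-LRP sets
#'
#' A gene is called a candidate for a class if it appears in strictly more
#' than `freq_threshold` of that class's per-sample quantitative-LRP sets
#' (computed on the gene-count feature space).
#'
#' @param sets Tibble from [quantitative_lrp_set()] for one class.
#' @param n_sets Number of per-sample sets considered (defaults to the
#'   distinct samples present in `sets`).
#' @param freq_threshold Strict frequency threshold (the study grid is 0.2,
#'   0.1, 0.02).
#' @return Tibble `feature`, `n_samples`, `frequency`, filtered to
#'   candidates, ordered by descending frequency.
#' @export
driver_candidates <- function(sets, n_sets = NULL, freq_threshold = 0.2) {
  if (is.null(n_sets)) n_sets <- dplyr::n_distinct(sets$sample_id)
  if (n_sets == 0L) {
    return(tibble::tibble(feature = character(), n_samples = integer(),
                          frequency = numeric()))
  }
  tab <- dplyr::summarise(dplyr::group_by(sets, .data$feature),
                          n_samples = dplyr::n_distinct(.data$sample_id),
                          .groups = "drop")
  tab$frequency <- tab$n_samples / n_sets
  dplyr::arrange(
    dplyr::filter(tab, .data$frequency > freq_threshold),
    dplyr::desc(.data$frequency))
}

#' Pixel-flipping accuracy curves
#'
#' Deletes input features in a given order (per-sample descending absolute
#' relevance by default, or seeded random orders) by setting them to the
#' training mean (zero in standardized space) and records the accuracy after
#' each deletion step. If relevance genuinely explains the classifier,
#' relevance-ordered deletion degrades accuracy at least as fast as random
#' deletion.
#'
#' @param network A `trained_network`.
#' @param features Feature tibble.
#' @param truth Character vector of true labels aligned with `features`
#'   rows.
#' @param relevance Optional raw relevance tibble aligned with `features`
#'   (computed with `target = "predicted"` if omitted).
#' @param steps Integer vector of deletion counts (default every 10th up to
#'   all features).
#' @param n_random Number of seeded random deletion orders to average.
#' @param seed Seed for the random orders.
#' @param epsilon LRP stabilizer for the default relevance computation.
#' @return Tibble `order` (`"relevance"` or `"random"`), `n_removed`,
#'   `accuracy` (random rows are averaged over the `n_random` orders).
#' @export
pixel_flipping <- function(network, features, truth, relevance = NULL,
                           steps = NULL, n_random = 10L, seed = 1L,
                           epsilon = 1e-6) {
  p <- length(network$feature_names)
  if (is.null(steps)) steps <- unique(c(seq(0L, p, by = 10L), p))
  if (is.null(relevance)) {
    relevance <- lrp_epsilon(network, features, epsilon = epsilon)
  }
  R <- as.matrix(relevance[network$feature_names])
  X <- as.matrix(features[network$feature_names])
  storage.mode(X) <- "double"
  X <- sweep(sweep(X, 2L, network$center), 2L, network$scale, "/")
  n <- nrow(X)
  y <- match(truth, network$classes)

  acc_for_orders <- function(ord_mat) {
    vapply(steps, function(k) {
      Xk <- X
      if (k > 0L) {
        for (i in seq_len(n)) Xk[i, ord_mat[i, seq_len(k)]] <- 0
      }
      logits <- .forward(network, Xk, n_hidden = network$n_hidden)$logits
      mean(max.col(logits, ties.method = "first") == y)
    }, numeric(1))
  }

  ord_rel <- t(apply(abs(R), 1L, order, decreasing = TRUE))
  rel_acc <- acc_for_orders(ord_rel)
  withr::local_seed(seed)
  rand_acc <- matrix(0, n_random, length(steps))
  for (r in seq_len(n_random)) {
    ord_r <- t(vapply(seq_len(n), function(i) sample.int(p), integer(p)))
    rand_acc[r, ] <- acc_for_orders(ord_r)
  }
  dplyr::bind_rows(
    tibble::tibble(order = "relevance", n_removed = steps, accuracy = rel_acc),
    tibble::tibble(order = "random", n_removed = steps,
                   accuracy = colMeans(rand_acc)))
}
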