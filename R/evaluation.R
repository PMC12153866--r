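#' Confusion matrix and one-vs-rest classification metrics
#'
#' Computes the predicted-by-true confusion table and, per class one-vs-rest,
#' precision TP/(TP+FP), recall TP/(TP+FN), the F1 score (harmonic mean of
#' the two) and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)), plus their
#' unweighted macro means. Zero-denominator ratios are reported as 0 and
#' flagged in the `degenerate` column rather than returned as NaN.
#'
#' @param truth,predicted Aligned label vectors.
#' @return A `metrics_report` list: `confusion` (tibble `truth`, `predicted`,
#'   `n`), `metrics` (per-class tibble with TP/FP/TN/FN, precision, recall,
#'   f1, mcc, degenerate), `macro` (one-row tibble of macro means).
#' @export
confusion_and_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("confusion_and_metrics(): length mismatch")
  }
  classes <- sort(unique(c(truth, predicted)))
  conf <- dplyr::count(tibble::tibble(truth = truth, predicted = predicted),
                       .data$truth, .data$predicted)
  n <- length(truth)
  rows <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    tn <- n - tp - fp - fn
    safe <- function(num, den) if (den == 0) 0 else num / den
    precision <- safe(tp, tp + fp)
    recall <- safe(tp, tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
    mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
    degenerate <- (tp + fp) == 0 || (tp + fn) == 0 || mcc_den == 0
    tibble::tibble(class = cl, tp = tp, fp = fp, tn = tn, fn = fn,
                   precision = precision, recall = recall, f1 = f1,
                   mcc = mcc, degenerate = degenerate)
  })
  metrics <- dplyr::bind_rows(rows)
  macro <- tibble::tibble(
    precision = mean(metrics$precision), recall = mean(metrics$recall),
    f1 = mean(metrics$f1), mcc = mean(metrics$mcc),
    accuracy = mean(truth == predicted))
  structure(list(confusion = conf, metrics = metrics, macro = macro),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", nrow(x$metrics), " classes\n", sep = "")
  cat(sprintf("  macro: precision %.3f, recall %.3f, F1 %.3f, MCC %.3f\n",
              x$macro$precision, x$macro$recall, x$macro$f1, x$macro$mcc))
  invisible(x)
}

#' @rdname confusion_and_metrics
#' @param x A `metrics_report`.
#' @export
tidy.metrics_report <- function(x, ...) x$metrics

#' @rdname confusion_and_metrics
#' @export
glance.metrics_report <- function(x, ...) x$macro

#' Rank-sum tests on each class's most relevant features
#'
#' For each class and each of its top-relevance features, tests the
#' per-sample feature counts of the class against all other classes pooled
#' (two-sided Wilcoxon rank-sum) and pairwise against every other class,
#' with Holm-Bonferroni adjustment of the p-values within each pairwise
#' family (one family per class/feature).
#'
#' @param features Feature tibble (`sample_id` + numeric columns).
#' @param labels Label tibble.
#' @param top_features Tibble `class`, `feature` naming the features to test
#'   per class (e.g. the top 5 by positive median relevance).
#' @param class Class column name in `labels`.
#' @return List of two tibbles: `vs_rest` (`class`, `feature`, `p`) and
#'   `pairwise` (`class`, `feature`, `other`, `p`, `p_holm`). Classes with
#'   fewer than 2 samples are skipped.
#' @export
top_feature_tests <- function(features, labels, top_features,
                              class = "cancer_type") {
  cls <- labels[[class]][match(features$sample_id, labels$sample_id)]
  sizes <- table(cls)
  vs_rest <- list(); pairwise <- list()
  for (i in seq_len(nrow(top_features))) {
    cl <- top_features$class[i]; f <- top_features$feature[i]
    if (is.na(sizes[cl]) || sizes[cl] < 2L) next
    x <- features[[f]][cls == cl]
    y <- features[[f]][cls != cl]
    p_rest <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    vs_rest[[length(vs_rest) + 1L]] <- tibble::tibble(
      class = cl, feature = f, p = p_rest)
    others <- setdiff(names(sizes)[sizes >= 2L], cl)
    if (length(others)) {
      pp <- vapply(others, function(o) {
        stats::wilcox.test(x, features[[f]][cls == o],
                           exact = FALSE)$p.value
      }, numeric(1))
      pairwise[[length(pairwise) + 1L]] <- tibble::tibble(
        class = cl, feature = f, other = others, p = unname(pp),
        p_holm = unname(stats::p.adjust(pp, method = "holm")))
    }
  }
  list(vs_rest = dplyr::bind_rows(vs_rest),
       pairwise = dplyr::bind_rows(pairwise))
}

#' Unsupervised baselines: z-score PCA and clustering
#'
#' Standardizes each feature to zero mean and unit variance (constant
#' columns dropped), computes principal components, and partitions the
#' samples with average-linkage agglomerative clustering and with k-means,
#' both under the Euclidean distance.
#'
#' @param features Feature tibble (`sample_id` + numeric columns; typically
#'   the 96 trinucleotide features).
#' @param k_clusters Number of clusters for both partitions.
#' @param seed Seed for the k-means starts.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List: `scores` (tibble `sample_id`, `PC1`, ... plus cluster
#'   assignments `hclust`, `kmeans`), `var_explained` (per-component
#'   fraction), `pca` (the `prcomp` object).
#' @export
unsupervised_baselines <- function(features, k_clusters = 2L, seed = 1L,
                                   linkage = "average") {
  if (nrow(features) < 2L) stop("unsupervised_baselines(): need >= 2 samples")
  if (k_clusters > nrow(features)) {
    stop("unsupervised_baselines(): more clusters than samples")
  }
  X <- as.matrix(features[setdiff(names(features), "sample_id")])
  storage.mode(X) <- "double"
  keep <- apply(X, 2L, stats::sd) > 0
  Z <- scale(X[, keep, drop = FALSE])
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  hc <- stats::cutree(stats::hclust(stats::dist(Z), method = linkage),
                      k = k_clusters)
  withr::local_seed(seed)
  km <- stats::kmeans(Z, centers = k_clusters, nstart = 10L)
  scores <- tibble::as_tibble(pca$x[, seq_len(min(10L, ncol(pca$x))),
                                    drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = features$sample_id), scores)
  scores$hclust <- unname(hc)
  scores$kmeans <- unname(km$cluster)
  list(scores = scores, var_explained = ve, pca = pca)
}
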