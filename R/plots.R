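#' Plot an informative mutational signature
#'
#' Bars show the mean 96-context mutation frequency profile, grouped and
#' colored by substitution class; bar transparency encodes the positive
#' median LRP relevance, so tall opaque bars are both frequent and decisive
#' for the class.
#'
#' @param object An `informative_signature`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.informative_signature <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mono <- sub("^.\\[(.+)\\].$", "\\1", df$context)
  df$context <- factor(df$context, levels = sbs96_contexts())
  rel <- df$relevance
  df$rel_scaled <- if (max(rel) > 0) rel / max(rel) else 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$context, y = .data$frequency,
                                   fill = .data$mono,
                                   alpha = .data$rel_scaled)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~mono, scales = "free_x", space = "free_x") +
    ggplot2::scale_alpha_continuous(range = c(0.35, 1),
                                    name = "relative\nrelevance") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "mutation frequency",
                  title = attr(object, "cancer_type")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Plot a training log
#'
#' @param object A `trained_network`.
#' @param ... Unused.
#' @return A ggplot object showing per-epoch validation accuracy with the
#'   kept epoch marked.
#' @export
autoplot.trained_network <- function(object, ...) {
  df <- object$log
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch,
                                   y = .data$val_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "validation accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a tile heatmap
#'
#' @param report A `metrics_report` from [confusion_and_metrics()].
#' @return A ggplot object; tiles show row-normalized prediction
#'   frequencies (per true class).
#' @export
plot_confusion <- function(report) {
  conf <- dplyr::mutate(dplyr::group_by(report$confusion, .data$truth),
                        frac = .data$n / sum(.data$n))
  ggplot2::ggplot(conf, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                     fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "#fdf6ec", high = "#b30000",
                                 limits = c(0, 1), name = "fraction") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
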