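#' Plot a hyperbolic embedding as a polar disc
#'
#' Nodes at their (r, theta) positions; colour by cluster label when a
#' clustering tibble is supplied.
#'
#' @param coords Tibble `id`, `r`, `theta`.
#' @param clusters Optional clustering tibble (`id`, `cluster`) from
#'   [cluster_by_gap()].
#' @param w Angular span.
#' @return A ggplot object.
#' @export
plot_hyperbolic_map <- function(coords, clusters = NULL, w = 2 * pi) {
  dat <- tibble::as_tibble(coords)
  if (!is.null(clusters)) {
    dat <- dplyr::left_join(dat, clusters[, c("id", "cluster")], by = "id") |>
      dplyr::mutate(cluster = factor(.data$cluster))
  }
  dat <- dplyr::mutate(dat,
                       x = .data$r * cos(.data$theta * 2 * pi / w),
                       y = .data$r * sin(.data$theta * 2 * pi / w))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (is.null(clusters)) {
    p + ggplot2::geom_point(size = 0.6, alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster),
                            size = 0.6, alpha = 0.8) +
      ggplot2::guides(colour = ggplot2::guide_legend(
        override.aes = list(size = 2)))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve of a model evaluation
#'
#' @param object A `ptm_eval` object.
#' @param ... Unused.
#' @return A ggplot object showing the ROC step curve, the chance diagonal
#'   and the AUC in the subtitle.
#' @export
autoplot.ptm_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "ROC curve",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Cross-validation accuracy distribution of a trained forest
#'
#' @param object A `ptm_rf` model.
#' @param ... Unused.
#' @return A ggplot object: per-repeat boxplots of held-out fold accuracy.
#' @export
autoplot.ptm_rf <- function(object, ...) {
  ggplot2::ggplot(object$cv,
                  ggplot2::aes(x = factor(.data$repeat_),
                               y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$cv_accuracy,
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "Cross-validation repeat", y = "Held-out accuracy") +
    ggplot2::theme_minimal()
}

#' Bar chart of permutation feature importance
#'
#' @param importance Tibble from [feature_importance()].
#' @return A ggplot object.
#' @export
plot_feature_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = .data$importance,
                               y = stats::reorder(.data$feature,
                                                  .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean accuracy drop under permutation", y = NULL) +
    ggplot2::theme_minimal()
}
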