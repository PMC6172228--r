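# ggplot2 presentation layer. Core functions only emit tibbles; these
# autoplot methods render the standard figures (ROC curves, score vs
# Hamming-distance humanization trajectories, score distributions).

#' @export
autoplot.mg_roc <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.humanization <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hd_to_origin,
                                   y = .data$score_after)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = "Hamming distance to origin", y = "MG score",
      title = sprintf("%s humanization trajectory", object$method)) +
    ggplot2::theme_minimal()
}

#' Boxplot of score distributions across labelled sets
#'
#' Convenience figure comparing score distributions (MG or distance
#' scores) across datasets, with an optional frozen threshold line.
#'
#' @param scores Tibble with a score column and a `set` column.
#' @param score_col Name of the score column.
#' @param threshold Optional horizontal threshold line.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(scores, score_col = "mg_score",
                                     threshold = NULL) {
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = .data$set,
                                    y = .data[[score_col]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = score_col) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed")
  p
}
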