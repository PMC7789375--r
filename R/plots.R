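#' ROC curve of a cross-validation result
#'
#' Plots the ROC curve computed from the pooled held-out scores, with
#' the chance diagonal and the AUC in the subtitle.
#'
#' @param object A `circ_cv` from [repeated_kfold_cv()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot circ_cv
#' @export
autoplot.circ_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166AC", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC, %s, %d x %d-fold CV", object$algorithm,
                      object$repeats, object$k),
      subtitle = sprintf("AUC = %.4f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Feature-combination grid plot
#'
#' Mean CV accuracy per feature-block combination and algorithm.
#'
#' @param object A `circ_grid` from [feature_combination_grid()].
#' @param metric Metric column to plot (default `"accuracy"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot circ_grid
#' @export
autoplot.circ_grid <- function(object, metric = "accuracy", ...) {
  df <- tibble::as_tibble(object)
  df$combination <- stats::reorder(df$combination, df[[metric]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combination,
                                   y = .data[[metric]],
                                   colour = .data$algorithm,
                                   group = .data$algorithm)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "Feature combination", y = paste("Mean CV", metric)) +
    ggplot2::theme_minimal()
}

#' Precision-recall curve of a cross-validation result
#'
#' @param cv A `circ_cv`.
#' @return A ggplot.
#' @export
plot_pr_curve <- function(cv) {
  stopifnot(inherits(cv, "circ_cv"))
  ggplot2::ggplot(cv$pr, ggplot2::aes(x = .data$recall,
                                      y = .data$precision)) +
    ggplot2::geom_path(colour = "#B2182B", linewidth = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("Precision-recall, %s", cv$algorithm)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
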