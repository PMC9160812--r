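#' Coefficient profiles of an L1 logistic path
#'
#' @param object A `scms_lasso_path`.
#' @param ... Unused.
#' @return A ggplot: per-gene coefficient trajectories against
#'   `log10(lambda)`.
#' @method autoplot scms_lasso_path
#' @export
autoplot.scms_lasso_path <- function(object, ...) {
  df <- tidy.scms_lasso_path(object)
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$lambda), .data$estimate,
                                   group = .data$gene,
                                   colour = .data$gene)) +
    ggplot2::geom_line(show.legend = length(object$genes) <= 12) +
    ggplot2::labs(x = "log10(lambda)", y = "coefficient",
                  title = "L1 logistic coefficient path") +
    ggplot2::theme_minimal()
}

#' Cross-validation deviance curve
#'
#' @param object A `scms_lasso_cv`.
#' @param ... Unused.
#' @return A ggplot: mean held-out binomial deviance with one-standard-error
#'   ribbon, with the `lambda_min` and `lambda_1se` choices marked.
#' @method autoplot scms_lasso_cv
#' @export
autoplot.scms_lasso_cv <- function(object, ...) {
  df <- tidy.scms_lasso_cv(object)
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$lambda), .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                      ymax = .data$estimate + .data$std.error),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(c(object$lambda_min,
                                             object$lambda_1se)),
                        linetype = c("solid", "dashed")) +
    ggplot2::labs(x = "log10(lambda)", y = "binomial deviance (held out)",
                  title = "Cross-validated L1 logistic path") +
    ggplot2::theme_minimal()
}

#' Score distribution by true label
#'
#' @param scores Tibble from [score_cells()] (columns `cell_id`, `scms`).
#' @param labels True per-cell labels aligned with `scores`.
#' @param cutoff Optional classification cut-point to mark.
#' @return A ggplot of the per-class scMS distributions.
#' @export
plot_score_distribution <- function(scores, labels, cutoff = NULL) {
  df <- dplyr::mutate(scores, label = labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$scms, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "single-cell malignant score (scMS)", y = "cells") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  }
  p
}
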