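#' Tidy a fitted malignancy model
#'
#' @param x An `scms_model`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate` (the intercept first).
#' @method tidy scms_model
#' @export
tidy.scms_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' One-row summary of a fitted malignancy model
#'
#' @param x An `scms_model`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `cutoff`, and the training `auc`,
#'   `sensitivity`, `specificity` when recorded.
#' @method glance scms_model
#' @export
glance.scms_model <- function(x, ...) {
  tm <- x$training_metrics
  tibble::tibble(
    n_genes = length(x$coefficients),
    cutoff = x$cutoff,
    auc = tm$auc %||% NA_real_,
    sensitivity = tm$sensitivity %||% NA_real_,
    specificity = tm$specificity %||% NA_real_
  )
}

#' Tidy an L1 logistic path
#'
#' @param x A `scms_lasso_path` (or `scms_lasso_cv`).
#' @param ... Unused.
#' @return Long tibble with `lambda`, `gene`, `estimate` (one row per gene
#'   and grid point).
#' @method tidy scms_lasso_path
#' @export
tidy.scms_lasso_path <- function(x, ...) {
  tibble::tibble(
    lambda = rep(x$lambda, each = length(x$genes)),
    gene = rep(x$genes, times = length(x$lambda)),
    estimate = as.vector(x$beta)
  )
}

#' Tidy a cross-validated L1 logistic path
#'
#' @param x A `scms_lasso_cv`.
#' @param ... Unused.
#' @return Tibble with `lambda`, `estimate` (mean held-out deviance),
#'   `std.error`, `nonzero`.
#' @method tidy scms_lasso_cv
#' @export
tidy.scms_lasso_cv <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    estimate = x$cv_mean_deviance,
    std.error = x$cv_se,
    nonzero = x$nonzero
  )
}

#' @rdname tidy.scms_lasso_cv
#' @return `glance()` gives one row with `lambda_min`, `lambda_1se` and the
#'   deviance minimum.
#' @method glance scms_lasso_cv
#' @export
glance.scms_lasso_cv <- function(x, ...) {
  tibble::tibble(
    lambda_min = x$lambda_min,
    lambda_1se = x$lambda_1se,
    min_cv_deviance = min(x$cv_mean_deviance)
  )
}
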