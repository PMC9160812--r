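#' L1-penalized binomial logistic regression path
#'
#' Minimizes the per-observation-average negative binomial log-likelihood
#' plus `lambda * sum(|beta_j|)` (intercept unpenalized) over a decreasing
#' lambda grid, by cyclic coordinate descent with soft-thresholding on the
#' iteratively reweighted quadratic approximation, warm starts along the
#' grid, and active-set iteration. With the per-observation loss convention,
#' `lambda_max = max_j |<x_j, y - mean(y)>| / n` is the smallest penalty at
#' which every penalized coefficient is zero.
#'
#' @param x Numeric design matrix, cells in rows and genes in columns, with
#'   each column scaled to mean 0, sd 1 (checked unless
#'   `check_scaled = FALSE`; fitting on fold subsets of a scaled matrix
#'   passes the tolerance).
#' @param y Binary response (0/1 or logical); 1 = malignant.
#' @param lambda Optional decreasing grid of penalties. By default, `nlambda`
#'   log-spaced values from `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio Grid size and span (defaults 100, 1e-4).
#' @param tol Convergence tolerance on the maximum weighted squared
#'   coefficient change per sweep, `max_j v_j (delta beta_j)^2` with
#'   `v_j = sum(w x_j^2)/n` (the criterion coordinate-descent solvers in
#'   this field use).
#' @param maxit Budget of coordinate updates per lambda (each an O(n)
#'   operation).
#' @param devmax Saturation stop: once the fraction of null deviance
#'   explained exceeds this, the path repeats that solution over the
#'   remaining grid (pushing lambda further on a near-saturated fit only
#'   inflates coefficients toward separation).
#' @param check_scaled Verify per-column mean/sd (tolerance 0.2).
#' @return An object of class `scms_lasso_path`: list with `lambda`,
#'   `a0` (per-lambda intercepts), `beta` (gene-by-lambda coefficient
#'   matrix), `nonzero` (per-lambda support size), `genes`, `n`.
#' @export
fit_l1_logistic_path <- function(x, y, lambda = NULL, nlambda = 100,
                                 lambda_min_ratio = 1e-4, tol = 1e-7,
                                 maxit = 1e5, devmax = 0.95,
                                 check_scaled = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("`y` must contain both classes", call. = FALSE)
  if (nrow(x) != length(y)) stop("`x` rows must match `y`", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  if (check_scaled) {
    mu <- colMeans(x); sdev <- apply(x, 2, stats::sd)
    if (any(abs(mu) > 0.2) || any(abs(sdev - 1) > 0.2)) {
      stop("`x` columns must be scaled (mean 0, sd 1); see apply_scaling()",
           call. = FALSE)
    }
  }
  n <- nrow(x); p <- ncol(x)
  if (is.null(lambda)) {
    lmax <- lambda_max(x, y)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    if (is.unsorted(rev(lambda))) {
      stop("`lambda` grid must be strictly decreasing", call. = FALSE)
    }
  }
  fit <- l1_logistic_core(x, y, lambda, tol = tol, maxit = maxit,
                          devmax = devmax)
  structure(
    list(lambda = lambda, a0 = fit$a0, beta = fit$beta,
         nonzero = colSums(fit$beta != 0), dev_ratio = fit$dev_ratio,
         genes = colnames(x), n = n),
    class = "scms_lasso_path"
  )
}

#' Smallest penalty at which the L1 logistic model is empty
#'
#' @inheritParams fit_l1_logistic_path
#' @return `max_j |<x_j, y - mean(y)>| / n`.
#' @export
lambda_max <- function(x, y) {
  y <- as.numeric(y)
  max(abs(crossprod(x, y - mean(y)))) / nrow(x)
}

# coordinate-descent core (compiled) over a decreasing lambda grid
l1_logistic_core <- function(x, y, lambdas, tol = 1e-7, maxit = 1e5,
                             devmax = 0.95) {
  fit <- l1_logistic_core_cpp(x, y, lambdas, tol, maxit, devmax)
  dimnames(fit$beta) <- list(colnames(x), NULL)
  fit
}

#' Linear predictor / class probability along a fitted path
#'
#' @param object A `scms_lasso_path`.
#' @param newx Design matrix (cells x genes) on the scale the path was fit.
#' @param type `"link"` for the linear predictor, `"response"` for
#'   probabilities.
#' @param ... Unused.
#' @return Matrix, cells by lambda values.
#' @export
predict.scms_lasso_path <- function(object, newx,
                                    type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- sweep(as.matrix(newx) %*% object$beta, 2, object$a0, "+")
  if (type == "response") stats::plogis(eta) else eta
}

binomial_deviance <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Ten-fold cross-validation of the L1 logistic path
#'
#' Stratified folds (class proportions preserved), binomial deviance on the
#' held-out folds, mean and standard error per lambda. The grid is fixed by
#' a fit on the full data so all folds share it.
#'
#' @inheritParams fit_l1_logistic_path
#' @param n_folds Number of folds (default 10; each class must have at least
#'   `n_folds` members so every fold sees both classes).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `scms_lasso_cv` extending the full-data
#'   `scms_lasso_path` with `cv_mean_deviance`, `cv_se`, `lambda_min`,
#'   `lambda_1se`, `fold` (the per-cell fold assignment).
#' @export
cv_l1_logistic <- function(x, y, lambda = NULL, n_folds = 10, seed = 1,
                           nlambda = 100, lambda_min_ratio = 1e-4,
                           tol = 1e-7, devmax = 0.95, check_scaled = TRUE) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (n_folds < 2) stop("`n_folds` must be at least 2", call. = FALSE)
  if (min(table(y)) < n_folds) {
    stop("stratified ", n_folds, "-fold CV impossible: smallest class has ",
         min(table(y)), " cells", call. = FALSE)
  }
  full <- fit_l1_logistic_path(x, y, lambda = lambda, nlambda = nlambda,
                               lambda_min_ratio = lambda_min_ratio, tol = tol,
                               devmax = devmax, check_scaled = check_scaled)
  lambda <- full$lambda
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  })
  dev <- matrix(NA_real_, n_folds, length(lambda))
  for (f in seq_len(n_folds)) {
    train <- fold != f
    fit <- fit_l1_logistic_path(x[train, , drop = FALSE], y[train],
                                lambda = lambda, tol = tol, devmax = devmax,
                                check_scaled = FALSE)
    prob <- predict(fit, x[!train, , drop = FALSE], type = "response")
    dev[f, ] <- apply(prob, 2, function(pp) binomial_deviance(y[!train], pp))
  }
  cv_mean <- colMeans(dev)
  cv_se <- apply(dev, 2, stats::sd) / sqrt(n_folds)
  # consider only grid points where the full-data path is actually estimated
  # (beyond saturation the solver repeats the last solution; those points are
  # not candidate models, mirroring how reference solvers end the path there)
  valid <- seq_len(max(which(cumsum(full$dev_ratio > devmax) <= 1)))
  i_min <- valid[which.min(cv_mean[valid])]
  within_1se <- valid[cv_mean[valid] <= cv_mean[i_min] + cv_se[i_min]]
  out <- full
  out$cv_mean_deviance <- cv_mean
  out$cv_se <- cv_se
  out$lambda_min <- lambda[i_min]
  out$lambda_1se <- lambda[min(within_1se)] # grid is decreasing: largest lambda
  out$fold <- fold
  class(out) <- c("scms_lasso_cv", "scms_lasso_path")
  out
}

#' Choose a penalty and the selected gene set from a cross-validated path
#'
#' Rules: `"cv_min"` takes the lambda of minimal mean held-out deviance;
#' `"cv_1se"` the largest lambda whose mean deviance is within one standard
#' error of that minimum; `"target_support"` the largest lambda at which
#' exactly `support` coefficients are non-zero.
#'
#' @param cv A `scms_lasso_cv` from [cv_l1_logistic()].
#' @param rule Selection rule.
#' @param support Required support size for `rule = "target_support"`.
#' @return A list of class `scms_selection`: `chosen_lambda`, `rule`,
#'   `selected_genes`, `coefficients` (named, non-zero only), `intercept`.
#' @export
select_lambda <- function(cv, rule = c("cv_min", "cv_1se", "target_support"),
                          support = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(cv, "scms_lasso_cv"))
  lam <- switch(rule,
    cv_min = cv$lambda_min,
    cv_1se = cv$lambda_1se,
    target_support = {
      if (is.null(support)) stop("`support` required", call. = FALSE)
      hit <- which(cv$nonzero == support)
      if (!length(hit)) {
        stop("no lambda on the grid attains support size ", support,
             "; attained sizes: ",
             paste(sort(unique(cv$nonzero)), collapse = ", "), call. = FALSE)
      }
      cv$lambda[min(hit)]
    }
  )
  k <- which(cv$lambda == lam)[1]
  b <- cv$beta[, k]
  sel <- names(b)[b != 0]
  structure(
    list(chosen_lambda = lam, rule = rule, selected_genes = sel,
         coefficients = b[b != 0], intercept = cv$a0[k]),
    class = "scms_selection"
  )
}

#' @export
print.scms_lasso_path <- function(x, ...) {
  cat(sprintf("<scms_lasso_path> %d genes, %d lambda values (%.4g .. %.4g)\n",
              length(x$genes), length(x$lambda), max(x$lambda), min(x$lambda)))
  if (!is.null(x$cv_mean_deviance)) {
    cat(sprintf("  cv: lambda_min = %.4g, lambda_1se = %.4g\n",
                x$lambda_min, x$lambda_1se))
  }
  invisible(x)
}

#' @export
print.scms_selection <- function(x, ...) {
  cat(sprintf("<scms_selection> rule %s at lambda = %.4g: %d gene(s)\n",
              x$rule, x$chosen_lambda, length(x$selected_genes)))
  cat(" ", paste(x$selected_genes, collapse = ", "), "\n")
  invisible(x)
}
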