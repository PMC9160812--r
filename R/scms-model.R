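#' Fit the final unpenalized logistic malignancy model
#'
#' Maximum-likelihood binomial logistic regression (IRLS via [stats::glm()])
#' of the malignancy label on the scaled expression of the selected genes.
#' Perfect separation (diverging coefficients) is detected and raises an
#' error by default; `ridge_on_separation = TRUE` falls back to a lightly
#' L2-regularized IRLS fit instead.
#'
#' @param x A [cell_matrix()] that has been through [apply_scaling()] (its
#'   `$scaling` statistics are embedded in the model so new data can be
#'   scored on the training population's scale).
#' @param genes Genes to include (default: all genes in `x`).
#' @param ridge_on_separation Fall back to ridge (penalty `1e-4`) when the
#'   classes are separable.
#' @return An object of class `scms_model`: list with `intercept`,
#'   `coefficients` (named numeric), `scaling` (tibble `gene`, `mean`, `sd`),
#'   `cutoff` (`NA` until [choose_cutoff()]), `training_metrics`,
#'   `provenance`.
#' @export
fit_final_logistic <- function(x, genes = NULL, ridge_on_separation = FALSE) {
  stopifnot(inherits(x, "cell_matrix"))
  if (x$values_kind != "scaled" || is.null(x$scaling)) {
    stop("`x` must be scaled with apply_scaling() so the model can carry ",
         "its scaling statistics", call. = FALSE)
  }
  if (is.null(genes)) genes <- rownames(x$values)
  if (length(genes) < 1) stop("at least one gene required", call. = FALSE)
  xm <- t(x$values[genes, , drop = FALSE])
  y <- malignant_indicator(x)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, xm), y,
                   family = stats::binomial())
  )
  coefs <- fit$coefficients
  separated <- !fit$converged || any(abs(coefs) > 30) ||
    any(fit$fitted.values > 1 - 1e-10 & y == 0) ||
    any(fit$fitted.values < 1e-10 & y == 1)
  if (separated) {
    if (!ridge_on_separation) {
      stop("perfect separation detected (diverging coefficients); refit with ",
           "`ridge_on_separation = TRUE` or revisit the gene set",
           call. = FALSE)
    }
    coefs <- ridge_logistic(xm, y, penalty = 1e-4)
  }
  scaling <- x$scaling[match(genes, x$scaling$gene), ]
  new_scms_model(
    intercept = unname(coefs[1]),
    coefficients = stats::setNames(unname(coefs[-1]), genes),
    scaling = scaling,
    provenance = "fitted by scmalig::fit_final_logistic"
  )
}

# IRLS with an L2 penalty on the slopes (not the intercept)
ridge_logistic <- function(xm, y, penalty = 1e-4, maxit = 100, tol = 1e-10) {
  xd <- cbind(1, xm)
  p <- ncol(xd)
  pen <- diag(c(0, rep(penalty, p - 1)))
  b <- numeric(p)
  for (i in seq_len(maxit)) {
    eta <- drop(xd %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    bn <- solve(crossprod(xd, w * xd) / length(y) + 2 * pen,
                crossprod(xd, w * z) / length(y))
    if (max(abs(bn - b)) < tol) { b <- drop(bn); break }
    b <- drop(bn)
  }
  stats::setNames(b, c("(Intercept)", colnames(xm)))
}

new_scms_model <- function(intercept, coefficients, scaling = NULL,
                           cutoff = NA_real_, training_metrics = NULL,
                           provenance = "") {
  if (!is.null(scaling)) {
    stopifnot(setequal(scaling$gene, names(coefficients)))
  }
  structure(
    list(intercept = intercept, coefficients = coefficients,
         scaling = scaling, cutoff = cutoff,
         training_metrics = training_metrics, provenance = provenance),
    class = "scms_model"
  )
}

#' @export
print.scms_model <- function(x, ...) {
  cat(sprintf("<scms_model> %d gene(s), intercept %.4f, cutoff %s\n",
              length(x$coefficients), x$intercept,
              ifelse(is.na(x$cutoff), "unset", format(x$cutoff))))
  cat("  genes:", paste(names(x$coefficients), collapse = ", "), "\n")
  if (is.null(x$scaling)) {
    cat("  scaling statistics: ABSENT - attach with attach_scaling()\n")
  }
  invisible(x)
}

#' The packaged seven-gene lung adenocarcinoma reference model
#'
#' The printed seven-gene malignancy signature: intercept -4.7082 and
#' coefficients KRT18 0.8449, IRX2 0.7221, NAPSA 1.2584, SPINK13 2.3251,
#' KRT7 1.5488, CAPN8 0.4969, GPRC5A 0.6344, with classification cut-point
#' scMS >= 0.046. The model ships deliberately without scaling statistics:
#' its inputs are per-gene z-scores, and the reference population's means
#' and dispersions are not published, so the user must supply scaling fitted
#' on their own population (see [attach_scaling()]) before scoring.
#'
#' @return An `scms_model` with `scaling = NULL`.
#' @examples
#' reference_model()
#' @export
reference_model <- function() {
  new_scms_model(
    intercept = -4.7082,
    coefficients = c(KRT18 = 0.8449, IRX2 = 0.7221, NAPSA = 1.2584,
                     SPINK13 = 2.3251, KRT7 = 1.5488, CAPN8 = 0.4969,
                     GPRC5A = 0.6344),
    scaling = NULL,
    cutoff = 0.046,
    provenance = "seven-gene lung adenocarcinoma reference signature"
  )
}

#' Attach per-gene scaling statistics to a score model
#'
#' @param model An `scms_model`.
#' @param stats Scaling statistics from [fit_scaling()] covering all of the
#'   model's genes.
#' @return The model with scaling for exactly its genes.
#' @export
attach_scaling <- function(model, stats) {
  stopifnot(inherits(model, "scms_model"),
            all(c("gene", "mean", "sd") %in% names(stats)))
  genes <- names(model$coefficients)
  idx <- match(genes, stats$gene)
  if (anyNA(idx)) {
    stop("scaling statistics missing for: ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  model$scaling <- tibble::as_tibble(stats[idx, c("gene", "mean", "sd")])
  model
}

#' Score cells with a malignancy model
#'
#' Applies the model's scaling to the cells' normalized expression, computes
#' the linear predictor `x = intercept + sum(coef_g * z_g)` and the
#' single-cell malignant score `scms = 1 / (1 + exp(-x))`, and classifies a
#' cell malignant iff `scms >= cutoff` (inclusive).
#'
#' @param model An `scms_model` with scaling statistics attached.
#' @param x A [cell_matrix()] with normalized values (a matrix already
#'   flagged `"scaled"` is used as-is, assuming it was scaled with the
#'   model's statistics).
#' @param impute_missing Replace genes absent from the matrix by scaled 0
#'   (population mean) with a warning instead of erroring.
#' @return Tibble with columns `cell_id`, `scms`, `predicted_label`
#'   (`NA` when the model has no cutoff).
#' @examples
#' m <- simulate_cells(generator_config(n_malignant = 100, n_normal = 400,
#'                                      n_noise_genes = 0, seed = 2))
#' mod <- attach_scaling(reference_model(), fit_scaling(m))
#' head(score_cells(mod, m))
#' @export
score_cells <- function(model, x, impute_missing = FALSE) {
  stopifnot(inherits(model, "scms_model"), inherits(x, "cell_matrix"))
  if (is.null(model$scaling)) {
    stop("model has no scaling statistics; attach them with attach_scaling() ",
         "fitted on your population", call. = FALSE)
  }
  if (x$values_kind == "counts") {
    stop("matrix holds raw counts; lognormalize() it before scoring",
         call. = FALSE)
  }
  genes <- names(model$coefficients)
  present <- genes %in% rownames(x$values)
  if (any(!present) && !impute_missing) {
    stop("model genes absent from matrix: ",
         paste(genes[!present], collapse = ", "),
         " (set `impute_missing = TRUE` to score with scaled-zero imputation)",
         call. = FALSE)
  }
  if (any(!present)) {
    warning("imputing scaled 0 for missing gene(s): ",
            paste(genes[!present], collapse = ", "), call. = FALSE)
  }
  z <- matrix(0, length(genes), n_cells(x),
              dimnames = list(genes, colnames(x$values)))
  if (x$values_kind == "scaled") {
    z[present, ] <- x$values[genes[present], , drop = FALSE]
  } else {
    st <- model$scaling[match(genes[present], model$scaling$gene), ]
    sd_safe <- ifelse(st$sd == 0, 1, st$sd)
    z[present, ] <- (x$values[genes[present], , drop = FALSE] - st$mean) / sd_safe
  }
  lin <- drop(model$intercept + crossprod(z, model$coefficients))
  scms <- stats::plogis(lin)
  tibble::tibble(
    cell_id = colnames(x$values),
    scms = unname(scms),
    predicted_label = if (is.na(model$cutoff)) NA_character_ else {
      ifelse(scms >= model$cutoff, "malignant", "normal")
    }
  )
}

#' Youden-optimal probability cut-point for malignancy scores
#'
#' Delegates to [youden_cutpoint()] on the scores. Under low malignant
#' prevalence the optimal probability threshold lands far below 0.5.
#'
#' @param scms Numeric malignancy scores in (0, 1).
#' @param labels True labels (see [gene_auc()]).
#' @return The threshold (a probability).
#' @export
choose_cutoff <- function(scms, labels) {
  youden_cutpoint(scms, labels)$threshold
}

#' @rdname choose_cutoff
#' @param model An `scms_model`.
#' @param cutoff Probability in (0, 1).
#' @return `set_cutoff()` returns the model with the cutoff stored.
#' @export
set_cutoff <- function(model, cutoff) {
  stopifnot(inherits(model, "scms_model"), cutoff > 0, cutoff < 1)
  model$cutoff <- cutoff
  model
}

#' Evaluate a malignancy model on labeled cells
#'
#' @param model An `scms_model` with scaling (and, for sensitivity and
#'   specificity, a cutoff).
#' @param x A labeled [cell_matrix()] with normalized values.
#' @return One-row tibble with `auc`, `sensitivity`, `specificity` (the
#'   latter two at the model cutoff, `scms >= cutoff` inclusive).
#' @export
evaluate_model <- function(model, x) {
  scored <- score_cells(model, x)
  labels <- x$cells$label
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to evaluate", call. = FALSE)
  }
  pos <- labels == "malignant"
  auc <- gene_auc(scored$scms, labels)
  if (is.na(model$cutoff)) {
    sens <- NA_real_; spec <- NA_real_
  } else {
    pred <- scored$scms >= model$cutoff
    sens <- mean(pred[pos]); spec <- mean(!pred[!pos])
  }
  tibble::tibble(auc = auc, sensitivity = sens, specificity = spec)
}

# ---- serialization ----------------------------------------------------------

#' Serialize / restore a score model as JSON
#'
#' The JSON document has fields `version`, `intercept`, `coefficients`
#' (gene -> value), `scaling` (gene -> mean/sd, or null), `cutoff`,
#' `provenance`. Numeric values round-trip at full double precision.
#'
#' @param model An `scms_model`.
#' @param path File path.
#' @return `write_scms_model()` returns `path` invisibly;
#'   `read_scms_model()` the restored `scms_model`.
#' @export
write_scms_model <- function(model, path) {
  stopifnot(inherits(model, "scms_model"))
  doc <- list(
    version = "1",
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    scaling = if (is.null(model$scaling)) NULL else list(
      gene = model$scaling$gene,
      mean = model$scaling$mean,
      sd = model$scaling$sd
    ),
    cutoff = if (is.na(model$cutoff)) NULL else model$cutoff,
    provenance = model$provenance
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scms_model
#' @export
read_scms_model <- function(path) {
  doc <- jsonlite::read_json(path)
  scaling <- NULL
  if (!is.null(doc$scaling)) {
    scaling <- tibble::tibble(
      gene = unlist(doc$scaling$gene),
      mean = unlist(doc$scaling$mean),
      sd = unlist(doc$scaling$sd)
    )
  }
  new_scms_model(
    intercept = doc$intercept,
    coefficients = unlist(doc$coefficients),
    scaling = scaling,
    cutoff = if (is.null(doc$cutoff)) NA_real_ else doc$cutoff,
    provenance = if (is.null(doc$provenance)) "" else doc$provenance
  )
}
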