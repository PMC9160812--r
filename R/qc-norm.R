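#' Cell-level quality-control thresholds
#'
#' The retention rule is: keep a cell iff
#' `min_genes <= genes_detected <= max_genes` and
#' `mito_fraction <= max_mito_fraction`. Removal is strict on the violating
#' side -- a cell with exactly `min_genes` genes detected or a mitochondrial
#' fraction exactly at the maximum is retained. Defaults are the conventional
#' droplet scRNA-seq filters (200 / 7000 genes, 20% mitochondrial counts).
#'
#' @param min_genes,max_genes Bounds on genes detected per cell
#'   (`0 <= min_genes < max_genes`).
#' @param max_mito_fraction Maximum mitochondrial count fraction, in (0, 1].
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 7000,
                          max_mito_fraction = 0.20) {
  stopifnot(min_genes >= 0, min_genes < max_genes,
            max_mito_fraction > 0, max_mito_fraction <= 1)
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Filter cells on quality-control criteria
#'
#' @param x A [cell_matrix()] (its `genes_detected` and `mito_fraction`
#'   metadata are used; they are populated at construction).
#' @param thresholds A [qc_thresholds()].
#' @return A list with elements `matrix` (the filtered `cell_matrix`) and
#'   `removed` (tibble `cell_id`, `reason`; semicolon-joined when a cell
#'   violates several rules). Removing every cell triggers a warning, not an
#'   error.
#' @examples
#' m <- simulate_cells(generator_config(n_malignant = 20, n_normal = 80,
#'                                      n_noise_genes = 30, seed = 1))
#' qc <- qc_filter(m, qc_thresholds(min_genes = 5, max_genes = 100))
#' qc$removed
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "cell_matrix"), inherits(thresholds, "qc_thresholds"))
  if (n_cells(x) == 0) stop("empty matrix: no cells to filter", call. = FALSE)
  info <- x$cells
  low <- info$genes_detected < thresholds$min_genes
  high <- info$genes_detected > thresholds$max_genes
  mito <- info$mito_fraction > thresholds$max_mito_fraction
  bad <- low | high | mito
  reason <- purrr::pmap_chr(list(low, high, mito), function(l, h, m) {
    paste(c(if (l) "low_genes", if (h) "high_genes", if (m) "high_mito"),
          collapse = ";")
  })
  removed <- tibble::tibble(cell_id = info$cell_id[bad], reason = reason[bad])
  if (all(bad)) {
    warning("all cells removed by QC filtering", call. = FALSE)
  }
  out <- x
  out$values <- x$values[, !bad, drop = FALSE]
  out$cells <- info[!bad, ]
  list(matrix = out, removed = removed)
}

#' Depth-normalize and log-transform raw counts
#'
#' Scales every cell to a fixed total count (`target_sum`) and applies
#' `log(1 + x)`. The result is invariant to per-cell scalar multiplication
#' of the raw counts (sequencing-depth invariance).
#'
#' @param x A [cell_matrix()] with `values_kind = "counts"`.
#' @param target_sum Per-cell total after depth scaling (default 10,000).
#' @return A `cell_matrix` flagged `"normalized"`.
#' @export
lognormalize <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "cell_matrix"), target_sum > 0)
  if (x$values_kind != "counts") {
    stop("`lognormalize()` expects raw counts; values are already ",
         x$values_kind, call. = FALSE)
  }
  tot <- colSums(x$values)
  if (any(tot == 0)) {
    stop("cell(s) with zero total count: ",
         paste(colnames(x$values)[tot == 0], collapse = ", "), call. = FALSE)
  }
  out <- x
  out$values <- log1p(sweep(x$values, 2, tot / target_sum, "/"))
  out$values_kind <- "normalized"
  out
}

#' Per-gene scaling (z-score) statistics
#'
#' `fit_scaling()` records each gene's mean and standard deviation over a
#' stated population; `apply_scaling()` z-scores a matrix with those
#' statistics. Statistics fitted on a training population travel inside a
#' fitted [scms_model] so new cells are always scaled with the
#' model's own reference population.
#'
#' @param x A [cell_matrix()] with normalized values.
#' @param source_population Free-text identifier of the population the
#'   statistics describe.
#' @return `fit_scaling()` returns a tibble (`gene`, `mean`, `sd`) with a
#'   `source_population` attribute; degenerate genes (sd = 0) are flagged by
#'   `sd == 0`.
#' @export
fit_scaling <- function(x, source_population = "training") {
  stopifnot(inherits(x, "cell_matrix"))
  if (x$values_kind == "counts") {
    stop("scaling statistics must be fitted on normalized values", call. = FALSE)
  }
  v <- x$values
  stats <- tibble::tibble(
    gene = rownames(v),
    mean = unname(rowMeans(v)),
    sd = unname(apply(v, 1, stats::sd))
  )
  attr(stats, "source_population") <- source_population
  stats
}

#' @rdname fit_scaling
#' @param stats Scaling statistics from `fit_scaling()` (any data frame with
#'   columns `gene`, `mean`, `sd`).
#' @param clip Optional symmetric clip bound applied after scaling (e.g. 10);
#'   default `NULL`, no clipping.
#' @return `apply_scaling()` returns a `cell_matrix` restricted to the genes
#'   in `stats`, flagged `"scaled"`, with the statistics stored in
#'   `$scaling`. Genes with sd = 0 are scaled to all-zero with a warning.
#' @export
apply_scaling <- function(x, stats, clip = NULL) {
  stopifnot(inherits(x, "cell_matrix"),
            all(c("gene", "mean", "sd") %in% names(stats)))
  missing <- setdiff(stats$gene, rownames(x$values))
  if (length(missing)) {
    stop("genes in scaling statistics absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- x$values[stats$gene, , drop = FALSE]
  degenerate <- stats$sd == 0
  if (any(degenerate)) {
    warning("constant gene(s) scaled to zero: ",
            paste(stats$gene[degenerate], collapse = ", "), call. = FALSE)
  }
  sd_safe <- ifelse(degenerate, 1, stats$sd)
  z <- (v - stats$mean) / sd_safe
  z[degenerate, ] <- 0
  if (!is.null(clip)) z <- pmin(pmax(z, -clip), clip)
  out <- x
  out$values <- z
  out$values_kind <- "scaled"
  out$scaling <- tibble::as_tibble(stats[, c("gene", "mean", "sd")])
  out
}
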