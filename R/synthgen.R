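#' Gaussian mean shift achieving a target marginal AUC
#'
#' For two equal-variance Gaussian populations separated by a mean shift
#' \eqn{\Delta}, the ROC AUC of the raw value as a classifier is
#' \eqn{\Phi(\Delta / (\sigma\sqrt{2}))}. This inverts that relation:
#' \eqn{\Delta = \sigma \sqrt{2}\, \Phi^{-1}(\mathrm{AUC})}, giving the shift
#' the synthetic generator must plant so a gene's malignant-vs-normal
#' discriminability matches a requested AUC.
#'
#' @param target_auc Target AUC, strictly in (0.5, 1).
#' @param sd Common within-class standard deviation, > 0.
#' @return The mean shift (a positive number).
#' @examples
#' calibrate_auc_shift(0.927) # ~ 2.06
#' @export
calibrate_auc_shift <- function(target_auc, sd = 1) {
  if (!is.numeric(target_auc) || any(target_auc <= 0.5) || any(target_auc >= 1)) {
    stop("`target_auc` must lie strictly in (0.5, 1)", call. = FALSE)
  }
  if (!is.numeric(sd) || any(sd <= 0)) {
    stop("`sd` must be positive", call. = FALSE)
  }
  sd * sqrt(2) * stats::qnorm(target_auc)
}

#' Configuration for the synthetic single-cell generator
#'
#' Describes two labeled cell populations: a small set of informative genes
#' whose marginal malignant-vs-normal AUCs are controlled via
#' [calibrate_auc_shift()], plus identically distributed noise genes. The
#' defaults emulate the study design this package targets: roughly 10%
#' malignant prevalence and seven informative genes whose AUCs span
#' 0.725--0.927, surrounded by many uninformative genes.
#'
#' @param n_malignant,n_normal Cell counts per class (each >= 1).
#' @param informative_genes Data frame with columns `gene`, `target_auc`
#'   (strictly in (0.5, 1)) and `direction` (`"up"` or `"down"`); defaults to
#'   the seven-gene reference signature AUC spectrum.
#' @param n_noise_genes Count of uninformative genes (>= 0), named
#'   `NOISE0001`, ...
#' @param zero_inflation_rate Probability in `[0, 1)` that any entry is
#'   masked to zero (dropout), applied by independent Bernoulli draws.
#' @param base_mean,base_sd Baseline expression mean (non-negative) and
#'   within-class standard deviation (positive). The default `base_mean`
#'   keeps the zero-truncation mass negligible even for down-shifted genes.
#' @param mito_shape1,mito_shape2 Beta parameters of the per-cell
#'   mitochondrial-fraction draw (defaults give mean 5%).
#' @param values_kind Scale flag attached to the output; the generator draws
#'   on an abstract continuous scale, so `"normalized"` (the default) feeds
#'   screening directly, while `"counts"` marks the values for
#'   [lognormalize()].
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_malignant = 1000,
                             n_normal = 9000,
                             informative_genes = reference_auc_spectrum(),
                             n_noise_genes = 500,
                             zero_inflation_rate = 0,
                             base_mean = 3,
                             base_sd = 1,
                             mito_shape1 = 2,
                             mito_shape2 = 38,
                             values_kind = c("normalized", "counts"),
                             seed = 1L) {
  values_kind <- match.arg(values_kind)
  informative_genes <- tibble::as_tibble(informative_genes)
  stopifnot(
    n_malignant >= 1, n_normal >= 1, n_noise_genes >= 0,
    all(c("gene", "target_auc", "direction") %in% names(informative_genes)),
    zero_inflation_rate >= 0, zero_inflation_rate < 1,
    base_mean >= 0, base_sd > 0, mito_shape1 > 0, mito_shape2 > 0
  )
  if (nrow(informative_genes) > 0) {
    if (any(informative_genes$target_auc <= 0.5) ||
        any(informative_genes$target_auc >= 1)) {
      stop("every `target_auc` must lie strictly in (0.5, 1)", call. = FALSE)
    }
    if (!all(informative_genes$direction %in% c("up", "down"))) {
      stop('`direction` must be "up" or "down"', call. = FALSE)
    }
    if (anyDuplicated(informative_genes$gene)) {
      stop("informative gene names must be unique", call. = FALSE)
    }
  }
  structure(
    list(
      n_malignant = as.integer(n_malignant),
      n_normal = as.integer(n_normal),
      informative_genes = informative_genes,
      n_noise_genes = as.integer(n_noise_genes),
      zero_inflation_rate = zero_inflation_rate,
      base_mean = base_mean,
      base_sd = base_sd,
      mito_shape1 = mito_shape1,
      mito_shape2 = mito_shape2,
      values_kind = values_kind,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Marginal AUC spectrum of the seven-gene reference signature
#'
#' The per-gene malignant-vs-normal AUCs of the seven genes in the packaged
#' reference model (KRT18 0.927, NAPSA 0.921, KRT7 0.892, GPRC5A 0.864,
#' IRX2 0.835, CAPN8 0.806, SPINK13 0.725), used as the default set of
#' informative genes the generator plants.
#'
#' @return Tibble with columns `gene`, `target_auc`, `direction`.
#' @export
reference_auc_spectrum <- function() {
  tibble::tibble(
    gene = c("KRT18", "NAPSA", "KRT7", "GPRC5A", "IRX2", "CAPN8", "SPINK13"),
    target_auc = c(0.927, 0.921, 0.892, 0.864, 0.835, 0.806, 0.725),
    direction = "up"
  )
}

# hard cap so a mis-typed config fails loudly instead of exhausting memory
.max_generated_entries <- 2e8

#' Generate a labeled synthetic single-cell expression matrix
#'
#' Draws every gene as an equal-variance Gaussian truncated at zero.
#' Informative genes receive a malignant-vs-normal mean shift from
#' [calibrate_auc_shift()] (negative for `direction = "down"`); noise genes
#' are identically distributed in both classes. Optional dropout masks
#' entries to zero by independent Bernoulli draws, and per-cell
#' mitochondrial fractions come from a Beta draw. All randomness is governed
#' by `config$seed` in a fixed draw order (informative genes in config order,
#' then noise genes, then the dropout mask, then mitochondrial fractions), so
#' identical configs reproduce bit-identical matrices.
#'
#' @param config A [generator_config()].
#' @return A [cell_matrix()]; malignant cells come first in column order.
#' @examples
#' m <- simulate_cells(generator_config(n_malignant = 50, n_normal = 200,
#'                                      n_noise_genes = 10, seed = 7))
#' m
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_cells <- config$n_malignant + config$n_normal
  n_genes <- nrow(config$informative_genes) + config$n_noise_genes
  if (n_genes < 1) stop("config describes zero genes", call. = FALSE)
  if (as.double(n_genes) * n_cells > .max_generated_entries) {
    stop(sprintf(
      "requested matrix (%d genes x %d cells) exceeds the generator size cap",
      n_genes, n_cells), call. = FALSE)
  }
  labels <- rep(c("malignant", "normal"), c(config$n_malignant, config$n_normal))
  is_mal <- labels == "malignant"

  withr::with_seed(config$seed, {
    rows <- vector("list", n_genes)
    info <- config$informative_genes
    for (i in seq_len(nrow(info))) {
      shift <- calibrate_auc_shift(info$target_auc[i], config$base_sd)
      if (info$direction[i] == "down") shift <- -shift
      mu <- ifelse(is_mal, config$base_mean + shift, config$base_mean)
      rows[[i]] <- stats::rnorm(n_cells, mean = mu, sd = config$base_sd)
    }
    if (config$n_noise_genes > 0) {
      noise <- matrix(
        stats::rnorm(config$n_noise_genes * n_cells,
                     mean = config$base_mean, sd = config$base_sd),
        nrow = config$n_noise_genes, byrow = TRUE
      )
      for (j in seq_len(config$n_noise_genes)) {
        rows[[nrow(info) + j]] <- noise[j, ]
      }
    }
    values <- do.call(rbind, rows)
    values[values < 0] <- 0
    if (config$zero_inflation_rate > 0) {
      mask <- stats::runif(length(values)) < config$zero_inflation_rate
      values[mask] <- 0
    }
    mito <- stats::rbeta(n_cells, config$mito_shape1, config$mito_shape2)
  })

  gene_names <- c(
    config$informative_genes$gene,
    if (config$n_noise_genes > 0) {
      sprintf("NOISE%04d", seq_len(config$n_noise_genes))
    }
  )
  dimnames(values) <- list(gene_names, sprintf("cell%06d", seq_len(n_cells)))
  cell_matrix(values, labels, values_kind = config$values_kind,
              mito_fraction = mito)
}

#' Inject quality-control failures into a matrix
#'
#' Modifies designated cells so each violates exactly one QC rule: too few
#' genes detected (the cell's expression is zeroed beyond the first
#' `min_genes - 1` genes), too many genes detected (padding genes named
#' `PAD...` are appended with non-zero expression only in the designated
#' cells), or an excessive mitochondrial fraction (metadata raised above the
#' threshold). Cells are designated deterministically from the start of the
#' column order: the first `n_low_gene_cells` cells, then the next
#' `n_high_gene_cells`, then the next `n_high_mito_cells`, so designations
#' never overlap.
#'
#' @param x A [cell_matrix()].
#' @param n_low_gene_cells,n_high_gene_cells,n_high_mito_cells Counts of cells
#'   to corrupt per rule; their sum must not exceed the number of cells.
#' @param thresholds A [qc_thresholds()] the failures are constructed against.
#' @return A list with elements `matrix` (the corrupted `cell_matrix`) and
#'   `modified` (tibble `cell_id`, `reason`).
#' @export
inject_qc_failures <- function(x, n_low_gene_cells = 0, n_high_gene_cells = 0,
                               n_high_mito_cells = 0,
                               thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "cell_matrix"))
  total <- n_low_gene_cells + n_high_gene_cells + n_high_mito_cells
  if (total > n_cells(x)) {
    stop("more designated cells than cells in the matrix", call. = FALSE)
  }
  ids <- colnames(x$values)
  low_ids <- ids[seq_len(n_low_gene_cells)]
  high_ids <- ids[n_low_gene_cells + seq_len(n_high_gene_cells)]
  mito_ids <- ids[n_low_gene_cells + n_high_gene_cells +
                    seq_len(n_high_mito_cells)]

  values <- x$values
  if (n_low_gene_cells > 0) {
    keep <- seq_len(min(nrow(values), max(thresholds$min_genes - 1L, 0L)))
    zero_rows <- setdiff(seq_len(nrow(values)), keep)
    values[zero_rows, low_ids] <- 0
  }
  if (n_high_gene_cells > 0) {
    n_detected <- max(colSums(values != 0))
    n_pad <- thresholds$max_genes + 1L - min(colSums(values[, high_ids, drop = FALSE] != 0))
    if (n_pad > 0) {
      pad <- matrix(0, n_pad, ncol(values),
                    dimnames = list(sprintf("PAD%05d", seq_len(n_pad)),
                                    colnames(values)))
      pad[, high_ids] <- 1
      values <- rbind(values, pad)
    }
  }
  mito <- x$cells$mito_fraction
  names(mito) <- x$cells$cell_id
  mito[mito_ids] <- min(1, thresholds$max_mito_fraction + 0.05)

  out <- cell_matrix(values, x$cells$label, values_kind = x$values_kind,
                     mito_fraction = unname(mito))
  modified <- tibble::tibble(
    cell_id = c(low_ids, high_ids, mito_ids),
    reason = rep(c("low_genes", "high_genes", "high_mito"),
                 c(n_low_gene_cells, n_high_gene_cells, n_high_mito_cells))
  )
  list(matrix = out, modified = modified)
}
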