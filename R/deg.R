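#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mann-Whitney / Wilcoxon rank-sum test with midranks for ties. Below
#' `exact_limit` total observations and in the absence of ties the exact null
#' distribution is used; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param pos,neg Numeric score vectors for the two groups (each length >= 1).
#' @param exact_limit Maximum total sample size for the exact test.
#' @return Two-sided p-value.
#' @keywords internal
rank_sum_p <- function(pos, neg, exact_limit = 50) {
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 + n2 <= exact_limit) {
    p <- if (u > n1 * n2 / 2) {
      2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 == 0) return(1)
  z <- u - mu
  z <- z - sign(z) * 0.5 # continuity correction
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

#' Per-gene Wilcoxon rank-sum test between malignant and normal cells
#'
#' @param x A [cell_matrix()] with normalized values and at least two cells
#'   per class.
#' @param exact_limit Passed to the per-gene test; below this total cell
#'   count (and without ties) the exact null distribution is used.
#' @return Tibble with columns `gene`, `p_value`.
#' @export
wilcoxon_per_gene <- function(x, exact_limit = 50) {
  stopifnot(inherits(x, "cell_matrix"))
  is_mal <- x$cells$label == "malignant"
  if (sum(is_mal) < 2 || sum(!is_mal) < 2) {
    stop("need at least 2 cells per class", call. = FALSE)
  }
  p <- apply(x$values, 1, function(v) {
    rank_sum_p(v[is_mal], v[!is_mal], exact_limit)
  })
  tibble::tibble(gene = rownames(x$values), p_value = unname(p))
}

#' Per-gene log2 fold change between class means
#'
#' `log2((mean_malignant + pseudocount) / (mean_normal + pseudocount))`,
#' with means taken over normalized expression. At `pseudocount -> 0`,
#' `|log2FC| = 0.5` corresponds to raw mean ratios of about 1.41 and 0.71.
#'
#' @param x A [cell_matrix()] with normalized values.
#' @param pseudocount Positive stabilizer added to both means (default 1).
#' @return Tibble with columns `gene`, `mean_malignant`, `mean_normal`,
#'   `log2fc`.
#' @export
log2_fold_change <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "cell_matrix"), pseudocount > 0)
  is_mal <- x$cells$label == "malignant"
  if (!any(is_mal) || all(is_mal)) {
    stop("both classes must be present", call. = FALSE)
  }
  m1 <- rowMeans(x$values[, is_mal, drop = FALSE])
  m0 <- rowMeans(x$values[, !is_mal, drop = FALSE])
  tibble::tibble(
    gene = rownames(x$values),
    mean_malignant = unname(m1),
    mean_normal = unname(m0),
    log2fc = unname(log2((m1 + pseudocount) / (m0 + pseudocount)))
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Step-up adjusted values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression screen between malignant and normal cells
#'
#' Combines [wilcoxon_per_gene()], [log2_fold_change()] and [bh_adjust()]
#' into one per-gene table.
#'
#' @inheritParams wilcoxon_per_gene
#' @inheritParams log2_fold_change
#' @return Tibble with columns `gene`, `mean_malignant`, `mean_normal`,
#'   `log2fc`, `p_value`, `fdr`, `direction` (`"up"` iff `log2fc > 0`).
#' @examples
#' m <- simulate_cells(generator_config(n_malignant = 100, n_normal = 400,
#'                                      n_noise_genes = 20, seed = 3))
#' deg <- deg_screen(m)
#' head(dplyr::arrange(deg, fdr))
#' @export
deg_screen <- function(x, pseudocount = 1, exact_limit = 50) {
  fc <- log2_fold_change(x, pseudocount)
  pv <- wilcoxon_per_gene(x, exact_limit)
  dplyr::left_join(fc, pv, by = "gene") |>
    dplyr::mutate(
      fdr = bh_adjust(.data$p_value),
      direction = ifelse(.data$log2fc > 0, "up", "down")
    )
}

#' Filter a differential-expression table
#'
#' Keeps records with `fdr < fdr_max` (strict) and
#' `|log2fc| >= min_abs_log2fc` (inclusive).
#'
#' @param records Data frame with columns `fdr` and `log2fc` (e.g. from
#'   [deg_screen()]).
#' @param fdr_max FDR ceiling (strict), default 0.01.
#' @param min_abs_log2fc Minimum absolute log2 fold change (inclusive),
#'   default 0.5.
#' @return The filtered tibble (a subset of `records`).
#' @export
deg_filter <- function(records, fdr_max = 0.01, min_abs_log2fc = 0.5) {
  stopifnot(all(c("fdr", "log2fc") %in% names(records)))
  dplyr::filter(tibble::as_tibble(records),
                .data$fdr < fdr_max, abs(.data$log2fc) >= min_abs_log2fc)
}
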