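#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed from ranks (the Mann-Whitney
#' statistic divided by `n_pos * n_neg`), with midranks so tied
#' positive/negative pairs contribute half credit. Equivalent to the
#' all-pairs comparison fraction; no threshold enumeration.
#'
#' @param scores Numeric per-cell scores (higher = more malignant-like).
#' @param labels Per-cell labels: logical (`TRUE` = positive), 0/1, or
#'   `"malignant"`/`"normal"` with malignant as the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' gene_auc(c(3, 5, 1, 2, 4), c(1, 1, 0, 0, 0)) # 5/6
#' @export
gene_auc <- function(scores, labels) {
  pos <- as_positive_indicator(labels, length(scores))
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

as_positive_indicator <- function(labels, n) {
  if (length(labels) != n) {
    stop("`labels` must match `scores` in length", call. = FALSE)
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("malignant", "normal"))) {
      stop('character labels must be "malignant"/"normal"', call. = FALSE)
    }
    labels == "malignant"
  } else {
    as.logical(labels)
  }
}

#' Youden-optimal classification cut-point
#'
#' Finds the threshold maximizing Youden's J = sensitivity + specificity - 1
#' for the rule "positive iff score >= threshold". Candidate thresholds are
#' the midpoints between adjacent distinct scores plus minus/plus infinity
#' (the all-positive and all-negative rules); ties in J are broken toward
#' higher sensitivity, then toward the lower threshold.
#'
#' @inheritParams gene_auc
#' @return A list with `threshold`, `sensitivity`, `specificity`. Constant
#'   scores give `threshold = NaN` with the all-positive rule's sensitivity
#'   and specificity, plus a warning.
#' @examples
#' youden_cutpoint(c(3, 5, 1, 2, 4), c(1, 1, 0, 0, 0))
#' @export
youden_cutpoint <- function(scores, labels) {
  pos <- as_positive_indicator(labels, length(scores))
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  u <- sort(unique(scores))
  if (length(u) == 1) {
    warning("constant scores: cut-point undefined; reporting all-positive rule",
            call. = FALSE)
    return(list(threshold = NaN, sensitivity = 1, specificity = 0))
  }
  cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  # counts of scores >= t via cumulative tallies over the sorted unique values
  pos_tab <- rev(cumsum(rev(tabulate(match(scores[pos], u), length(u)))))
  neg_tab <- rev(cumsum(rev(tabulate(match(scores[!pos], u), length(u)))))
  # cand[k] (k >= 2) lies just below u[k]: scores >= cand[k] <=> score >= u[k]
  sens <- c(n1, pos_tab[-1], 0) / n1
  spec <- 1 - c(n2, neg_tab[-1], 0) / n2
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[sens[best] == max(sens[best])]
  best <- best[which.min(cand[best])]
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' Per-gene ROC records
#'
#' Computes, for each requested gene, the malignant-vs-normal AUC of its
#' expression, the orientation-corrected AUC `max(auc, 1 - auc)`, the
#' direction (`"up"` iff `auc >= 0.5`), and the Youden-optimal sensitivity,
#' specificity and threshold on the oriented score (down-regulated genes are
#' negated before cut-point search so sensitivity/specificity are reported on
#' the discriminating orientation, the convention used when tabulating gene
#' panels).
#'
#' @param x A [cell_matrix()] with normalized values.
#' @param genes Gene names to evaluate (default: all genes).
#' @return Tibble with columns `gene`, `auc`, `auc_oriented`, `direction`,
#'   `sensitivity`, `specificity`, `threshold`.
#' @export
gene_roc <- function(x, genes = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(genes)) genes <- rownames(x$values)
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing)) {
    stop("genes absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labels <- x$cells$label
  purrr::map_dfr(genes, function(g) {
    sc <- x$values[g, ]
    auc <- gene_auc(sc, labels)
    up <- auc >= 0.5
    cp <- youden_cutpoint(if (up) sc else -sc, labels)
    tibble::tibble(
      gene = g, auc = auc, auc_oriented = max(auc, 1 - auc),
      direction = ifelse(up, "up", "down"),
      sensitivity = cp$sensitivity, specificity = cp$specificity,
      threshold = cp$threshold
    )
  })
}

#' AUC screen for tumor-cell discriminating genes
#'
#' Retains genes whose oriented AUC strictly exceeds `auc_min` (default
#' 0.60): a gene with AUC exactly at the floor is dropped. Down-regulated
#' discriminators are retained through the orientation correction and
#' reported with `direction = "down"`.
#'
#' @inheritParams gene_roc
#' @param auc_min Strict lower bound on the oriented AUC.
#' @return Tibble of retained [gene_roc()] records, ordered by decreasing
#'   oriented AUC.
#' @export
roc_screen <- function(x, genes = NULL, auc_min = 0.60) {
  gene_roc(x, genes) |>
    dplyr::filter(.data$auc_oriented > auc_min) |>
    dplyr::arrange(dplyr::desc(.data$auc_oriented))
}
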