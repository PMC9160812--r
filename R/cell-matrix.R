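#' Labeled gene-by-cell expression container
#'
#' A `cell_matrix` bundles a dense gene-by-cell expression matrix (genes in
#' rows, cells in columns -- the orientation is fixed at every interface of
#' this package) with per-cell metadata: the binary malignancy label and the
#' two quality-control covariates, number of genes detected and mitochondrial
#' count fraction.
#'
#' @param values Numeric matrix, genes in rows (unique rownames) and cells in
#'   columns (unique colnames). Non-negative and finite when `values_kind`
#'   is `"counts"`.
#' @param labels Character vector, one of `"malignant"`/`"normal"` per cell.
#' @param values_kind One of `"counts"` (raw), `"normalized"`
#'   (depth-normalized log scale or any per-gene comparable scale) or
#'   `"scaled"` (per-gene z-scores).
#' @param mito_fraction Optional per-cell mitochondrial fraction in `[0, 1]`.
#'   When absent it is computed from `values` using genes whose name starts
#'   with `mito_prefix` (0 if there are none).
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#'
#' @return An object of class `cell_matrix`: a list with elements `values`,
#'   `cells` (a tibble with columns `cell_id`, `label`, `genes_detected`,
#'   `mito_fraction`), `values_kind`, and optionally `scaling` (set by
#'   [apply_scaling()]).
#' @examples
#' m <- cell_matrix(
#'   matrix(rpois(20, 5), 4, 5,
#'          dimnames = list(paste0("g", 1:4), paste0("c", 1:5))),
#'   labels = c("malignant", "malignant", "normal", "normal", "normal")
#' )
#' m
#' @export
cell_matrix <- function(values, labels,
                        values_kind = c("counts", "normalized", "scaled"),
                        mito_fraction = NULL, mito_prefix = "MT-") {
  values_kind <- match.arg(values_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x cells)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("gene names must be unique", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("cell ids must be unique", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  if (values_kind == "counts" && any(values < 0)) {
    stop("raw counts must be non-negative", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop("number of labels must equal number of cells", call. = FALSE)
  }
  if (!all(labels %in% c("malignant", "normal"))) {
    stop('labels must be "malignant" or "normal"', call. = FALSE)
  }
  if (is.null(mito_fraction)) {
    mito_fraction <- compute_mito_fraction(values, mito_prefix)
  }
  stopifnot(length(mito_fraction) == ncol(values),
            all(mito_fraction >= 0 & mito_fraction <= 1))
  cells <- tibble::tibble(
    cell_id = colnames(values),
    label = labels,
    genes_detected = as.integer(colSums(values != 0)),
    mito_fraction = as.numeric(mito_fraction)
  )
  structure(
    list(values = values, cells = cells, values_kind = values_kind),
    class = "cell_matrix"
  )
}

compute_mito_fraction <- function(values, mito_prefix = "MT-") {
  mito <- startsWith(rownames(values), mito_prefix)
  if (!any(mito)) return(rep(0, ncol(values)))
  tot <- colSums(values)
  frac <- rep(0, ncol(values))
  frac[tot > 0] <- colSums(values[mito, , drop = FALSE])[tot > 0] / tot[tot > 0]
  frac
}

#' @export
print.cell_matrix <- function(x, ...) {
  n_mal <- sum(x$cells$label == "malignant")
  cat(sprintf(
    "<cell_matrix> %d genes x %d cells (%d malignant, %d normal), values: %s\n",
    nrow(x$values), ncol(x$values), n_mal, ncol(x$values) - n_mal,
    x$values_kind
  ))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' Number of genes / cells in a `cell_matrix`
#' @param x A [cell_matrix()].
#' @return Integer count.
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname n_genes
#' @export
n_cells <- function(x) ncol(x$values)

#' Per-cell metadata of a `cell_matrix` as a tibble
#' @param x A [cell_matrix()].
#' @return Tibble with columns `cell_id`, `label`, `genes_detected`,
#'   `mito_fraction`.
#' @export
cell_info <- function(x) x$cells

#' Subset a `cell_matrix` by gene names and/or cell ids
#'
#' @param x A [cell_matrix()].
#' @param genes,cells Character vectors of gene names / cell ids to keep
#'   (default: keep all). Unknown names raise an error.
#' @return A `cell_matrix` restricted to the requested genes and cells.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(genes)) genes <- rownames(x$values)
  if (is.null(cells)) cells <- colnames(x$values)
  missing_g <- setdiff(genes, rownames(x$values))
  if (length(missing_g)) {
    stop("genes absent from matrix: ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  }
  missing_c <- setdiff(cells, colnames(x$values))
  if (length(missing_c)) {
    stop("cells absent from matrix: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  out <- x
  out$values <- x$values[genes, cells, drop = FALSE]
  out$cells <- x$cells[match(cells, x$cells$cell_id), ]
  out
}

malignant_indicator <- function(x) {
  as.integer(x$cells$label == "malignant")
}

# ---- readers / writers ------------------------------------------------------

#' Write / read a `cell_matrix` as a 10x-style Matrix Market triplet
#'
#' Writes `matrix.mtx` (genes x cells, sparse triplet), `features.tsv` and
#' `barcodes.tsv` into `dir`, plus `labels.tsv` (`cell_id<TAB>label`).
#'
#' @param x A [cell_matrix()].
#' @param dir Output / input directory.
#' @param values_kind Value scale flag to attach on read (the Matrix Market
#'   format does not carry it).
#' @return `write_cell_matrix_10x()` returns `dir` invisibly;
#'   `read_cell_matrix_10x()` returns a `cell_matrix`.
#' @export
write_cell_matrix_10x <- function(x, dir) {
  stopifnot(inherits(x, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(x$values, "sparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene = rownames(x$values)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(cell_id = colnames(x$values)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  write_cell_labels(x, file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' @rdname write_cell_matrix_10x
#' @export
read_cell_matrix_10x <- function(dir, values_kind = "counts") {
  mm <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  feats <- readr::read_tsv(file.path(dir, "features.tsv"), col_names = "gene",
                           show_col_types = FALSE)
  bars <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "cell_id",
                          show_col_types = FALSE)
  dimnames(mm) <- list(feats$gene, bars$cell_id)
  labels <- read_cell_labels(file.path(dir, "labels.tsv"), bars$cell_id)
  cell_matrix(mm, labels, values_kind = values_kind)
}

#' Write / read a `cell_matrix` as dense TSV (genes in rows)
#'
#' @param x A [cell_matrix()].
#' @param path Matrix TSV path; the companion label file is
#'   `<path>.labels.tsv` unless given.
#' @param labels_path Two-column TSV `cell_id<TAB>label`.
#' @param values_kind Value scale flag to attach on read.
#' @return `write_cell_matrix_tsv()` returns `path` invisibly;
#'   `read_cell_matrix_tsv()` a `cell_matrix`.
#' @export
write_cell_matrix_tsv <- function(x, path,
                                  labels_path = paste0(path, ".labels.tsv")) {
  stopifnot(inherits(x, "cell_matrix"))
  df <- tibble::as_tibble(x$values, rownames = "gene")
  readr::write_tsv(df, path)
  write_cell_labels(x, labels_path)
  invisible(path)
}

#' @rdname write_cell_matrix_tsv
#' @export
read_cell_matrix_tsv <- function(path,
                                 labels_path = paste0(path, ".labels.tsv"),
                                 values_kind = "counts") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  mm <- as.matrix(df[, -1])
  rownames(mm) <- df[[1]]
  labels <- read_cell_labels(labels_path, colnames(mm))
  cell_matrix(mm, labels, values_kind = values_kind)
}

write_cell_labels <- function(x, path) {
  readr::write_tsv(x$cells[, c("cell_id", "label")], path, col_names = FALSE)
  invisible(path)
}

read_cell_labels <- function(path, cell_ids) {
  lab <- readr::read_tsv(path, col_names = c("cell_id", "label"),
                         show_col_types = FALSE)
  if (!setequal(lab$cell_id, cell_ids)) {
    stop("label file cell ids do not match matrix cells", call. = FALSE)
  }
  lab$label[match(cell_ids, lab$cell_id)]
}
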