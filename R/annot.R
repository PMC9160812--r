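#' Load a subcellular-localization annotation table
#'
#' Reads a TSV with columns `gene` and `locations` (semicolon-separated
#' subcellular-location terms) and flags genes encoding secreted or
#' membrane-bound proteins: the flag is true iff the gene's terms intersect
#' `secreted_membrane_terms`. Gene symbols are upper-cased. A small synthetic
#' table covering the reference-signature genes ships with the package (see
#' the example); a full Human Protein Atlas subcellular export in the same
#' two-column layout can be supplied instead.
#'
#' @param path TSV path.
#' @param secreted_membrane_terms Location terms counted as secreted or
#'   membrane-bound.
#' @return Tibble with columns `gene`, `locations` (character), and
#'   `secreted_or_membrane` (logical).
#' @examples
#' tab <- load_annotation(
#'   system.file("extdata", "gene_localization_synthetic.tsv",
#'               package = "scmalig"))
#' dplyr::filter(tab, secreted_or_membrane)
#' @export
load_annotation <- function(path,
                            secreted_membrane_terms = c(
                              "Secreted", "Membrane", "Plasma membrane",
                              "Cell membrane", "Cell Junctions")) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty annotation table: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2 || header[1] != "gene" || header[2] != "locations") {
    stop("annotation table must have header 'gene\\tlocations' (line 1)",
         call. = FALSE)
  }
  body <- fields[-1]
  bad <- which(vapply(body, length, 1L) < 1 |
                 !nzchar(vapply(body, `[`, "", 1)))
  if (length(bad)) {
    stop("malformed annotation row at line ", bad[1] + 1, call. = FALSE)
  }
  gene <- toupper(vapply(body, `[`, "", 1))
  locations <- vapply(body, function(f) {
    if (length(f) >= 2 && !is.na(f[2])) f[2] else ""
  }, "")
  terms <- strsplit(locations, ";", fixed = TRUE)
  flag <- vapply(terms, function(t) {
    any(trimws(t) %in% secreted_membrane_terms)
  }, logical(1))
  tibble::tibble(gene = gene, locations = locations,
                 secreted_or_membrane = flag)
}

#' Restrict genes to those encoding secreted or membrane-bound proteins
#'
#' @param genes Character vector of gene symbols.
#' @param annotation Annotation tibble from [load_annotation()].
#' @return The subset of `genes` flagged secreted-or-membrane. Genes missing
#'   from the annotation are excluded and listed in a warning.
#' @export
filter_secreted_membrane <- function(genes, annotation) {
  stopifnot(all(c("gene", "secreted_or_membrane") %in% names(annotation)))
  key <- toupper(genes)
  idx <- match(key, annotation$gene)
  unknown <- genes[is.na(idx)]
  if (length(unknown)) {
    warning("genes missing from annotation (excluded): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  genes[!is.na(idx) & annotation$secreted_or_membrane[replace(idx, is.na(idx), 1)]]
}
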