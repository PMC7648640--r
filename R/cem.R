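#' Construct a labelled single-cell count matrix
#'
#' The basic container of the package: a gene x cell matrix of raw counts
#' (UMIs or reads) together with one cell-type label and one donor label per
#' cell. Gene and cell identifiers live in the dimnames and must be unique.
#'
#' @param counts numeric gene x cell matrix (base or \pkg{Matrix} sparse),
#'   finite and non-negative, with unique rownames (genes) and colnames
#'   (cells).
#' @param cell_type character/factor vector, one label per cell.
#' @param donor character/factor vector, one label per cell.
#' @return an object of class `CellExpressionMatrix`: a list with elements
#'   `counts` (dense base matrix), `cell_type` and `donor` (character).
#' @export
cell_expression_matrix <- function(counts, cell_type, donor) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    .stopf("`counts` must be a numeric matrix")
  if (any(!is.finite(counts))) .stopf("`counts` contains non-finite values")
  if (any(counts < 0)) .stopf("`counts` contains negative values")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("`counts` needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts))) .stopf("gene ids are not unique")
  if (anyDuplicated(colnames(counts))) .stopf("cell ids are not unique")
  cell_type <- as.character(cell_type)
  donor <- as.character(donor)
  if (length(cell_type) != ncol(counts) || length(donor) != ncol(counts))
    .stopf("label vectors must have one entry per cell (%d cells)", ncol(counts))
  structure(list(counts = counts, cell_type = cell_type, donor = donor),
            class = "CellExpressionMatrix")
}

#' @export
print.CellExpressionMatrix <- function(x, ...) {
  cat(sprintf("CellExpressionMatrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$cell_type)
  cat(sprintf("  %d cell types: %s\n", length(tab),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d donors\n", length(unique(x$donor))))
  invisible(x)
}

#' @export
dim.CellExpressionMatrix <- function(x) dim(x$counts)

#' Subset a CellExpressionMatrix by genes and/or cells
#'
#' @param x a `CellExpressionMatrix`.
#' @param genes,cells logical/integer/character index vectors; `NULL` keeps
#'   everything.
#' @return the subsetted `CellExpressionMatrix` (attributes such as planted
#'   marker truth are carried over).
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "CellExpressionMatrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  if (is.character(ci)) ci <- match(ci, colnames(x$counts))
  out <- cell_expression_matrix(x$counts[gi, ci, drop = FALSE],
                                x$cell_type[ci], x$donor[ci])
  for (a in c("marker_truth", "synthetic_spec"))
    if (!is.null(attr(x, a))) attr(out, a) <- attr(x, a)
  out
}

gene_ids <- function(x) rownames(x$counts)
cell_ids <- function(x) colnames(x$counts)
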