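#' Read a labelled count matrix from disk
#'
#' Two on-disk layouts are supported. `format = "mtx"` expects the usual
#' triplet layout of droplet pipelines: `matrix.mtx` (Matrix Market,
#' genes x cells) next to `genes.tsv` (columns `id`, `symbol`) and
#' `cells.tsv` (columns `id`, `cell_type`, `donor`). `format = "delimited"`
#' expects a single table whose header row holds cell ids and whose first
#' column holds gene ids, plus a `cells.tsv` annotation beside it.
#'
#' @param path for `mtx`, the directory holding the three files (or the path
#'   of the `.mtx` file itself); for `delimited`, the matrix file.
#' @param format `"mtx"` or `"delimited"`.
#' @param cells_file,genes_file optional overrides for the annotation paths.
#' @return a [cell_expression_matrix()].
#' @export
read_counts <- function(path, format = c("mtx", "delimited"),
                        cells_file = NULL, genes_file = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(dir, "matrix.mtx") else path
    genes_file <- genes_file %||% file.path(dir, "genes.tsv")
    cells_file <- cells_file %||% file.path(dir, "cells.tsv")
    for (f in c(mtx, genes_file, cells_file))
      if (!file.exists(f)) .stopf("missing input file: %s", f)
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- data.table::fread(genes_file, header = TRUE, sep = "\t")
    cells <- data.table::fread(cells_file, header = TRUE, sep = "\t")
    if (!all(c("id", "cell_type", "donor") %in% names(cells)))
      .stopf("cells annotation must have columns id, cell_type, donor")
    if (nrow(genes) != nrow(m))
      .stopf("dimension mismatch: %d matrix rows vs %d gene annotations",
             nrow(m), nrow(genes))
    if (nrow(cells) != ncol(m))
      .stopf("dimension mismatch: %d matrix columns vs %d cell annotations",
             ncol(m), nrow(cells))
    rownames(m) <- as.character(genes[[1L]])
    colnames(m) <- as.character(cells$id)
    cell_expression_matrix(m, cells$cell_type, cells$donor)
  } else {
    if (!file.exists(path)) .stopf("missing input file: %s", path)
    dt <- data.table::fread(path, header = TRUE)
    m <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(m) <- as.character(dt[[1L]])
    cells_file <- cells_file %||% file.path(dirname(path), "cells.tsv")
    if (!file.exists(cells_file)) .stopf("missing annotation file: %s", cells_file)
    cells <- data.table::fread(cells_file, header = TRUE, sep = "\t")
    if (!all(c("id", "cell_type", "donor") %in% names(cells)))
      .stopf("cells annotation must have columns id, cell_type, donor")
    idx <- match(colnames(m), as.character(cells$id))
    if (anyNA(idx))
      .stopf("dimension mismatch: matrix cells missing from annotation (%s, ...)",
             colnames(m)[which(is.na(idx))[1L]])
    cell_expression_matrix(m, cells$cell_type[idx], cells$donor[idx])
  }
}

#' Write a labelled count matrix in the MTX + TSV layout read by
#' [read_counts()]
#'
#' @param x a `CellExpressionMatrix`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "CellExpressionMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  data.table::fwrite(data.table::data.table(id = gene_ids(x), symbol = gene_ids(x)),
                     file.path(dir, "genes.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(id = cell_ids(x),
                                            cell_type = x$cell_type,
                                            donor = x$donor),
                     file.path(dir, "cells.tsv"), sep = "\t")
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
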