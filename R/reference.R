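#' Build the reference (signature) matrix C
#'
#' Entry (g, k) is the arithmetic mean of the raw counts of gene g over the
#' training cells of cell type k. Columns follow sorted cell-type ids, so
#' the result is deterministic and invariant under cell reordering. The
#' reference is built un-transformed and un-normalized; transformations and
#' normalizations are applied downstream, the same way as for the mixtures.
#'
#' @param train a `CellExpressionMatrix` that passed QC.
#' @return a `ReferenceMatrix`: gene x cell-type numeric matrix with class
#'   attribute.
#' @export
build_reference <- function(train) {
  stopifnot(inherits(train, "CellExpressionMatrix"))
  types <- sort(unique(train$cell_type))
  C <- vapply(types, function(k)
    rowMeans(train$counts[, train$cell_type == k, drop = FALSE]),
    numeric(nrow(train$counts)))
  dimnames(C) <- list(gene_ids(train), types)
  structure(C, class = c("ReferenceMatrix", "matrix"))
}

#' Restrict a reference matrix to marker genes
#'
#' Rows are the union of all cell types' markers, de-duplicated, in the
#' reference's original gene order.
#'
#' @param C a [build_reference()] result (or any gene x type matrix with
#'   rownames).
#' @param markers a `MarkerSet`.
#' @return the row-subsetted `ReferenceMatrix`. Warns if the result loses
#'   full column rank.
#' @export
subset_to_markers <- function(C, markers) {
  stopifnot(inherits(markers, "MarkerSet"))
  genes <- unique(unlist(markers$markers, use.names = FALSE))
  if (!length(genes)) .stopf("empty MarkerSet: no genes to subset to")
  unknown <- setdiff(genes, rownames(C))
  if (length(unknown))
    .stopf("marker genes absent from reference: %s%s", unknown[1L],
           if (length(unknown) > 1L) sprintf(" (+%d more)", length(unknown) - 1L) else "")
  out <- C[rownames(C) %in% genes, , drop = FALSE]
  if (nrow(out) >= ncol(out) && qr(out)$rank < ncol(out))
    warning("marker-restricted reference is column rank deficient", call. = FALSE)
  structure(out, class = c("ReferenceMatrix", "matrix"))
}

#' Remove one cell type from a reference and its marker set
#'
#' For the bulk deconvolution path the removed type's marker genes leave the
#' signature too; with `drop_markers = FALSE` (the single-cell-reference
#' convention) only the column is removed and the gene set is untouched.
#'
#' @param C a `ReferenceMatrix`.
#' @param markers a `MarkerSet` (may be `NULL` with `drop_markers = FALSE`).
#' @param victim cell type to remove.
#' @param drop_markers drop the victim's marker genes from the set.
#' @return `list(reference = , markers = )`.
#' @export
drop_cell_type <- function(C, markers, victim, drop_markers = TRUE) {
  if (!victim %in% colnames(C))
    .stopf("cell type %s not present in the reference", victim)
  if (ncol(C) <= 1L) .stopf("dropping %s would leave an empty reference", victim)
  C2 <- structure(C[, colnames(C) != victim, drop = FALSE],
                  class = c("ReferenceMatrix", "matrix"))
  m2 <- markers
  if (!is.null(markers)) {
    stopifnot(inherits(markers, "MarkerSet"))
    m2$markers <- markers$markers[names(markers$markers) != victim]
    if (drop_markers) {
      gone <- markers$markers[[victim]]
      m2$markers <- lapply(m2$markers, function(g) setdiff(g, gone))
      m2$table <- m2$table[m2$table$cell_type != victim &
                             !(m2$table$gene %in% gone), , drop = FALSE]
    } else {
      m2$table <- m2$table[m2$table$cell_type != victim, , drop = FALSE]
    }
  }
  list(reference = C2, markers = m2)
}

#' Pairwise Pearson correlations between cell-type expression profiles
#'
#' @param C a `ReferenceMatrix` (optionally already marker-restricted via
#'   `markers`).
#' @param markers optional `MarkerSet`; when given, correlations use only
#'   the marker rows (`scope = "markers_only"`), otherwise all genes.
#' @return symmetric cell-type x cell-type correlation matrix with unit
#'   diagonal; constant profiles give `NA` off-diagonals.
#' @export
celltype_correlations <- function(C, markers = NULL) {
  if (ncol(C) < 2L) .stopf("need >= 2 cell types for pairwise correlations")
  M <- if (is.null(markers)) C else subset_to_markers(C, markers)
  R <- suppressWarnings(stats::cor(unclass(M)))
  diag(R) <- 1
  R
}
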