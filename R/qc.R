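#' Quality control for single-cell count matrices
#'
#' Applies, strictly in this order: (1) removal of all-zero and
#' zero-variance genes; (2) removal of cells whose library size,
#' mitochondrial fraction or ribosomal fraction lies more than `n_mads`
#' median absolute deviations from the corresponding median; (3) retention
#' of genes with a count greater than `min_count` in at least
#' `min_frac_cells` of the remaining cells, regardless of cell type;
#' (4) retention of cell types with at least `min_cells_per_type` remaining
#' cells. Interactions between rules are resolved by this order.
#'
#' MAD filtering operates on the raw library size and on linear
#' mitochondrial/ribosomal fractions and is two-sided by default; metrics
#' whose gene set is empty are skipped.
#'
#' @param x a [cell_expression_matrix()].
#' @param n_mads number of MADs beyond which a cell is an outlier.
#' @param min_frac_cells fraction of cells that must exceed `min_count`.
#' @param min_count count threshold of the gene filter (kept genes have
#'   counts strictly greater than this in enough cells).
#' @param min_cells_per_type minimum retained cells for a type to survive.
#' @param mito_genes,ribo_genes gene-id vectors; by default genes whose ids
#'   start with `MT-` (mitochondrial) or `RPL`/`RPS` (ribosomal).
#' @param mad_constant consistency constant of the MAD (1.4826 matches a
#'   normal sd).
#' @param two_sided if `FALSE`, only upper outliers are removed.
#' @return a list with elements `data` (filtered `CellExpressionMatrix`) and
#'   `report` (a `QCReport`: in/out dimensions, per-rule removal counts,
#'   dropped cell types).
#' @export
qc_filter <- function(x, n_mads = 3, min_frac_cells = 0.05, min_count = 1,
                      min_cells_per_type = 50,
                      mito_genes = NULL, ribo_genes = NULL,
                      mad_constant = 1.4826, two_sided = TRUE) {
  stopifnot(inherits(x, "CellExpressionMatrix"))
  counts <- x$counts
  n_genes_in <- nrow(counts); n_cells_in <- ncol(counts)
  g_ids <- rownames(counts)
  mito_genes <- mito_genes %||% g_ids[startsWith(g_ids, "MT-")]
  ribo_genes <- ribo_genes %||% g_ids[startsWith(g_ids, "RPL") | startsWith(g_ids, "RPS")]
  if (length(setdiff(mito_genes, g_ids)) || length(setdiff(ribo_genes, g_ids)))
    .stopf("mito/ribo gene sets must be subsets of the gene ids")

  removed <- c(zero_or_constant_gene = 0L, library_size = 0L,
               mito_fraction = 0L, ribo_fraction = 0L,
               low_prevalence_gene = 0L, small_cell_type = 0L)

  ## (1) all-zero / zero-variance genes
  rv <- .row_vars(counts)
  keep_g <- rv > 0
  removed["zero_or_constant_gene"] <- sum(!keep_g)
  counts <- counts[keep_g, , drop = FALSE]

  ## (2) MAD outlier cells on library size / mito / ribo fractions.
  ## Removing outliers shifts the median, so the rule is iterated to its
  ## fixed point; this is what makes the whole filter idempotent.
  out_by <- function(v) {
    med <- stats::median(v); s <- .mad(v, mad_constant)
    if (s == 0) return(rep(FALSE, length(v)))
    d <- (v - med) / s
    if (two_sided) abs(d) > n_mads else d > n_mads
  }
  ct <- x$cell_type; dn <- x$donor
  repeat {
    lib <- colSums(counts)
    bad_lib <- out_by(lib)
    frac_of <- function(set) {
      set <- intersect(set, rownames(counts))
      if (!length(set)) return(NULL)
      colSums(counts[set, , drop = FALSE]) / pmax(lib, 1)
    }
    mf <- frac_of(mito_genes); rf <- frac_of(ribo_genes)
    bad_mito <- if (is.null(mf)) rep(FALSE, ncol(counts)) else out_by(mf)
    bad_ribo <- if (is.null(rf)) rep(FALSE, ncol(counts)) else out_by(rf)
    removed["library_size"] <- removed["library_size"] + sum(bad_lib)
    removed["mito_fraction"] <- removed["mito_fraction"] + sum(bad_mito & !bad_lib)
    removed["ribo_fraction"] <- removed["ribo_fraction"] +
      sum(bad_ribo & !bad_lib & !bad_mito)
    keep_c <- !(bad_lib | bad_mito | bad_ribo)
    if (all(keep_c)) break
    counts <- counts[, keep_c, drop = FALSE]
    ct <- ct[keep_c]; dn <- dn[keep_c]
    if (ncol(counts) == 0L) .stopf("qc_filter removed every cell")
  }

  ## (3) prevalence gene filter (cell-type agnostic)
  prev <- rowMeans(counts > min_count)
  n_prev <- sum(prev < min_frac_cells)
  removed["low_prevalence_gene"] <- n_prev
  counts <- counts[prev >= min_frac_cells, , drop = FALSE]
  if (nrow(counts) == 0L) .stopf("qc_filter removed every gene")

  ## (4) drop small cell types
  tab <- table(ct)
  dropped_types <- names(tab)[tab < min_cells_per_type]
  keep_t <- !(ct %in% dropped_types)
  removed["small_cell_type"] <- sum(!keep_t)
  counts <- counts[, keep_t, drop = FALSE]
  ct <- ct[keep_t]; dn <- dn[keep_t]
  if (ncol(counts) == 0L) .stopf("qc_filter removed every cell type")

  ## rules (2)-(4) can re-expose zero-variance genes; the stated order is
  ## kept, so such genes survive until the next qc_filter call
  out <- cell_expression_matrix(counts, ct, dn)
  for (a in c("marker_truth", "synthetic_spec"))
    if (!is.null(attr(x, a))) attr(out, a) <- attr(x, a)
  report <- structure(list(
    n_genes_in = n_genes_in, n_genes_out = nrow(counts),
    n_cells_in = n_cells_in, n_cells_out = ncol(counts),
    cells_removed_by_rule = removed[c("library_size", "mito_fraction", "ribo_fraction",
                                      "small_cell_type")],
    genes_removed_by_rule = removed[c("zero_or_constant_gene", "low_prevalence_gene")],
    cell_types_dropped = dropped_types), class = "QCReport")
  list(data = out, report = report)
}

.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1L)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: genes %d -> %d, cells %d -> %d\n",
              x$n_genes_in, x$n_genes_out, x$n_cells_in, x$n_cells_out))
  cat("  cells removed:",
      paste(sprintf("%s=%d", names(x$cells_removed_by_rule), x$cells_removed_by_rule),
            collapse = ", "), "\n")
  cat("  genes removed:",
      paste(sprintf("%s=%d", names(x$genes_removed_by_rule), x$genes_removed_by_rule),
            collapse = ", "), "\n")
  if (length(x$cell_types_dropped))
    cat("  cell types dropped:", paste(x$cell_types_dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a QCReport as a two-column TSV
#' @param report a `QCReport`.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "QCReport"))
  kv <- c(n_genes_in = report$n_genes_in, n_genes_out = report$n_genes_out,
          n_cells_in = report$n_cells_in, n_cells_out = report$n_cells_out,
          stats::setNames(as.integer(report$cells_removed_by_rule),
                          paste0("cells_removed.", names(report$cells_removed_by_rule))),
          stats::setNames(as.integer(report$genes_removed_by_rule),
                          paste0("genes_removed.", names(report$genes_removed_by_rule))))
  dt <- data.table::data.table(key = names(kv), value = as.integer(kv))
  dt <- rbind(dt, data.table::data.table(
    key = "cell_types_dropped",
    value = paste(report$cell_types_dropped, collapse = ",")), fill = TRUE)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Split cells into balanced training and testing halves
#'
#' `by_cell` shuffles the cells of each cell type with the given seed and
#' divides them 50:50 (the extra cell of an odd count goes to training), so
#' both splits have a near-identical cell-type distribution. `by_donor`
#' first assigns half of the donors to each split (extra donor to training)
#' and then takes all their cells, so no donor contributes to both splits.
#'
#' @param x a `CellExpressionMatrix`.
#' @param mode `"by_cell"` or `"by_donor"`.
#' @param seed integer seed; a fixed seed gives identical splits.
#' @return `list(train = , test = )` of `CellExpressionMatrix`.
#' @export
split_train_test <- function(x, mode = c("by_cell", "by_donor"), seed = 1L) {
  stopifnot(inherits(x, "CellExpressionMatrix"))
  mode <- match.arg(mode)
  ids <- cell_ids(x)
  if (mode == "by_cell") {
    tab <- table(x$cell_type)
    if (any(tab < 2L))
      .stopf("by_cell split needs >= 2 cells per cell type (violated by: %s)",
             paste(names(tab)[tab < 2L], collapse = ", "))
    train_idx <- with_seed(seed, {
      unlist(lapply(sort(unique(x$cell_type)), function(k) {
        i <- which(x$cell_type == k)
        i <- sample(i)
        i[seq_len(ceiling(length(i) / 2))]
      }), use.names = FALSE)
    })
  } else {
    donors <- sort(unique(x$donor))
    if (length(donors) < 2L)
      .stopf("by_donor split needs >= 2 donors, got %d", length(donors))
    train_donors <- with_seed(seed, {
      d <- sample(donors)
      d[seq_len(ceiling(length(d) / 2))]
    })
    train_idx <- which(x$donor %in% train_donors)
  }
  train_idx <- sort(train_idx)
  list(train = subset_cells(x, cells = train_idx),
       test = subset_cells(x, cells = setdiff(seq_along(ids), train_idx)))
}
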