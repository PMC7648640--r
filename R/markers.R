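#' The eight marker selection strategies
#' @export
MARKER_STRATEGIES <- c("all", "pos_fc", "top_n2", "top_50p_logFC",
                       "bottom_50p_logFC", "top_50p_AveExpr",
                       "bottom_50p_AveExpr", "random5")

#' Per-gene, per-cell-type marker statistics
#'
#' Computes, on TMM-normalized log2 counts-per-million (pseudo-count 1), the
#' statistics that drive marker selection: the log2 fold change of each
#' cell type's mean against the second-highest-expressing type, the average
#' log-expression over all cells, a Welch two-sample t-test of the type
#' against all other cells (BH-adjusted across genes within each type) and
#' the fraction of the type's cells expressing the gene. Genes without a
#' positive count in at least `min_expr_frac` of the cells of at least one
#' type are excluded before testing.
#'
#' @param train a `CellExpressionMatrix` (the training split).
#' @param fc_threshold linear fold-change threshold recorded for selection
#'   (2 for pancreas-like, 1.8 for kidney-like, 1.5 for PBMC-like data).
#' @param alpha BH-adjusted p-value threshold recorded for selection.
#' @param min_expr_frac prevalence filter fraction.
#' @param fc_scale `"log"` compares mean log2 expressions (default);
#'   `"linear"` compares linear-scale type means with pseudo-count 1.
#' @return a `GeneStats` data.frame with columns `gene`, `cell_type`,
#'   `logFC`, `AveExpr`, `p_adj`, `frac_expressed`, carrying the thresholds
#'   as attributes.
#' @export
rank_genes <- function(train, fc_threshold = 2, alpha = 0.05,
                       min_expr_frac = 0.30, fc_scale = c("log", "linear")) {
  stopifnot(inherits(train, "CellExpressionMatrix"))
  fc_scale <- match.arg(fc_scale)
  types <- sort(unique(train$cell_type))
  K <- length(types)
  if (K < 2L) .stopf("rank_genes needs >= 2 cell types")
  tab <- table(train$cell_type)
  if (any(tab < 2L))
    .stopf("cell type with < 2 cells: %s", paste(names(tab)[tab < 2L], collapse = ", "))

  counts <- train$counts
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  logcpm <- log2(sweep(counts, 2L, eff, "/") * 1e6 + 1)

  expr_frac <- vapply(types, function(k)
    rowMeans(counts[, train$cell_type == k, drop = FALSE] > 0), numeric(nrow(counts)))
  keep <- apply(expr_frac, 1L, max) >= min_expr_frac
  if (!any(keep)) .stopf("no gene passes the %d%% prevalence filter",
                         round(100 * min_expr_frac))
  counts <- counts[keep, , drop = FALSE]
  logcpm <- logcpm[keep, , drop = FALSE]
  expr_frac <- expr_frac[keep, , drop = FALSE]
  G <- nrow(counts)

  mean_log <- vapply(types, function(k)
    rowMeans(logcpm[, train$cell_type == k, drop = FALSE]), numeric(G))
  mean_lin <- vapply(types, function(k)
    rowMeans(counts[, train$cell_type == k, drop = FALSE]), numeric(G))
  ave_expr <- rowMeans(logcpm)

  rows <- vector("list", K)
  for (ki in seq_len(K)) {
    k <- types[ki]
    ## fold change against the highest OTHER type (for the top-expressing
    ## type this is the second-highest overall)
    other_log <- apply(mean_log[, -ki, drop = FALSE], 1L, max)
    other_lin <- apply(mean_lin[, -ki, drop = FALSE], 1L, max)
    logfc <- if (fc_scale == "log") mean_log[, ki] - other_log
             else log2((mean_lin[, ki] + 1) / (other_lin + 1))
    p <- .welch_p(logcpm, train$cell_type == k)
    rows[[ki]] <- data.frame(
      gene = rownames(counts), cell_type = k, logFC = logfc,
      AveExpr = ave_expr, p_adj = stats::p.adjust(p, "BH"),
      frac_expressed = expr_frac[, ki], row.names = NULL,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_log") <- mean_log    # genes x types mean log2 CPM
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "alpha") <- alpha
  attr(out, "min_expr_frac") <- min_expr_frac
  class(out) <- c("GeneStats", "data.frame")
  out
}

## vectorized Welch two-sample t-test (group vs rest), two-sided p-values
.welch_p <- function(m, in_group) {
  x <- m[, in_group, drop = FALSE]; y <- m[, !in_group, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- .row_vars(x); v2 <- .row_vars(y)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1      # zero-variance genes: no evidence either way
  p
}

#' Select markers under one of the eight benchmark strategies
#'
#' The base marker set contains every gene with |logFC| at or above
#' log2(`fc_threshold`) and adjusted p below `alpha`, each gene assigned to
#' the single cell type with the largest |logFC| (ties prefer the positive
#' contrast, then type order). Negative-fold-change markers (genes
#' depleted in their type but high everywhere else) are part of `all` and
#' removed by `pos_fc`. Subsetting strategies act per cell type on the base
#' set: `top_n2` keeps the 2 largest logFC; the `*_50p_*` strategies keep
#' the upper ceiling(n/2) or lower floor(n/2) by logFC or AveExpr (ties
#' broken by AveExpr then gene id); `random5` draws 5 filter-passing genes
#' per type with the given seed (a negative control, ignoring the base
#' set).
#'
#' @param stats a [rank_genes()] result.
#' @param strategy one of `r paste(MARKER_STRATEGIES, collapse = ", ")`.
#' @param seed integer seed (used by `random5`).
#' @param fc_threshold,alpha override the thresholds recorded in `stats`.
#' @return a `MarkerSet`: list with `strategy`, `markers` (named list, cell
#'   type to ordered gene vector), `table` (the selected `GeneStats` rows)
#'   and `thresholds`.
#' @export
select_markers <- function(stats, strategy = MARKER_STRATEGIES, seed = 1L,
                           fc_threshold = NULL, alpha = NULL) {
  stopifnot(inherits(stats, "GeneStats"), nrow(stats) > 0L)
  strategy <- match.arg(strategy)
  fc_threshold <- fc_threshold %||% attr(stats, "fc_threshold")
  alpha <- alpha %||% attr(stats, "alpha")
  types <- sort(unique(stats$cell_type))

  base <- .base_markers(stats, fc_threshold, alpha)

  pick <- function(tb, strategy) {
    ord_fc <- order(-tb$logFC, -tb$AveExpr, tb$gene)
    ord_ae <- order(-tb$AveExpr, -tb$logFC, tb$gene)
    n <- nrow(tb)
    top <- ceiling(n / 2)
    switch(strategy,
      all = tb[ord_fc, , drop = FALSE],
      pos_fc = tb[ord_fc, , drop = FALSE][tb$logFC[ord_fc] > 0, , drop = FALSE],
      top_n2 = tb[ord_fc, , drop = FALSE][seq_len(min(2L, n)), , drop = FALSE],
      top_50p_logFC = tb[ord_fc, , drop = FALSE][seq_len(top), , drop = FALSE],
      bottom_50p_logFC = tb[ord_fc, , drop = FALSE][setdiff(seq_len(n), seq_len(top)), , drop = FALSE],
      top_50p_AveExpr = tb[ord_ae, , drop = FALSE][seq_len(top), , drop = FALSE],
      bottom_50p_AveExpr = tb[ord_ae, , drop = FALSE][setdiff(seq_len(n), seq_len(top)), , drop = FALSE])
  }

  if (strategy == "random5") {
    genes <- sort(unique(stats$gene))
    sel <- with_seed(seed, {
      lapply(stats::setNames(types, types), function(k) sort(sample(genes, 5L)))
    })
    table <- do.call(rbind, lapply(types, function(k) {
      tb <- stats[stats$cell_type == k & stats$gene %in% sel[[k]], , drop = FALSE]
      tb[order(tb$gene), , drop = FALSE]
    }))
  } else {
    picked <- lapply(stats::setNames(types, types), function(k) {
      tb <- base[base$cell_type == k, , drop = FALSE]
      if (nrow(tb) == 0L) {
        warning(sprintf("cell type %s has no base markers under strategy %s",
                        k, strategy), call. = FALSE)
        return(tb)
      }
      pick(tb, strategy)
    })
    sel <- lapply(picked, function(tb) tb$gene)
    table <- do.call(rbind, picked)
  }
  rownames(table) <- NULL
  structure(list(strategy = strategy, markers = sel, table = table,
                 thresholds = list(fc_threshold = fc_threshold, alpha = alpha)),
            class = "MarkerSet")
}

## Base marker assignment. A gene becomes a positive marker of the type
## whose mean exceeds the second-highest-expressing type by the fold
## threshold (at most one type can); if no type qualifies positively, it
## becomes a negative marker of the type it is depleted in (logFC at or
## below -log2(threshold): low in that type, high in all the others).
## Significance is required for the assigned contrast.
.base_markers <- function(stats, fc_threshold, alpha) {
  lfc_min <- log2(fc_threshold)
  sp <- split(seq_len(nrow(stats)), stats$gene)
  keep <- integer(0)
  for (idx in sp) {
    lfc <- stats$logFC[idx]
    ord <- order(-lfc, stats$cell_type[idx])
    best <- idx[ord[1L]]
    if (stats$logFC[best] >= lfc_min && stats$p_adj[best] < alpha) {
      keep <- c(keep, best)
      next
    }
    worst <- idx[order(lfc, stats$cell_type[idx])[1L]]
    if (stats$logFC[worst] <= -lfc_min && stats$p_adj[worst] < alpha)
      keep <- c(keep, worst)
  }
  stats[keep, , drop = FALSE]
}

#' @export
print.MarkerSet <- function(x, ...) {
  cat(sprintf("MarkerSet (%s): %d cell types, %d markers total\n",
              x$strategy, length(x$markers), length(unlist(x$markers))))
  for (k in names(x$markers))
    cat(sprintf("  %s: %d\n", k, length(x$markers[[k]])))
  invisible(x)
}

#' Serialize a MarkerSet as TSV
#' @param markers a `MarkerSet`.
#' @param path output file.
#' @export
write_marker_set <- function(markers, path) {
  stopifnot(inherits(markers, "MarkerSet"))
  tb <- markers$table
  tb$strategy <- markers$strategy
  data.table::fwrite(tb[, c("cell_type", "gene", "logFC", "AveExpr", "p_adj",
                            "strategy")], path, sep = "\t")
  invisible(path)
}

#' Percentage of markers that are not specific to a single cell type
#'
#' A marker of strategy `all`, found for its primary cell type (the one
#' with the highest fold change), counts as non-specific when, under the
#' same fold-change threshold, it would also qualify as a marker of a
#' secondary cell type — that is, some other type's mean exceeds the
#' highest remaining type (primary excluded) by the fold threshold. A
#' significance condition is deliberately not imposed on the secondary
#' contrast: the one-vs-rest test is powerless for the middle type of an
#' expression gradient, the very case this statistic is after. With only
#' two cell types there is no room for a secondary marker and the result
#' is 0.
#'
#' @param stats the [rank_genes()] result the markers came from.
#' @param markers a `MarkerSet` of strategy `"all"`.
#' @param fc_threshold linear fold-change threshold of the secondary check
#'   (defaults to the markers' own threshold).
#' @return percentage (0-100) of non-specific markers.
#' @export
marker_specificity <- function(stats, markers, fc_threshold = NULL) {
  stopifnot(inherits(stats, "GeneStats"), inherits(markers, "MarkerSet"))
  if (markers$strategy != "all")
    .stopf("marker_specificity expects markers from strategy 'all'")
  fc_threshold <- fc_threshold %||% markers$thresholds$fc_threshold
  lfc_min <- log2(fc_threshold)
  tb <- markers$table
  if (nrow(tb) == 0L) return(0)
  ml <- attr(stats, "mean_log")
  if (is.null(ml)) .stopf("stats lack the mean_log attribute; rerun rank_genes")
  types <- colnames(ml)
  if (length(types) < 3L) return(0)
  non_specific <- vapply(seq_len(nrow(tb)), function(i) {
    g <- tb$gene[i]; primary <- tb$cell_type[i]
    others <- setdiff(types, primary)
    any(vapply(others, function(k) {
      rest <- setdiff(others, k)
      ml[g, k] - max(ml[g, rest]) >= lfc_min
    }, logical(1)))
  }, logical(1))
  100 * mean(non_specific)
}
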