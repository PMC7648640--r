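## align an estimated proportion matrix to the ground truth: missing cell
## types count as estimated 0; mixtures with degenerate (NA) estimates are
## excluded and reported via the "n_used" attribute
.align_props <- function(P_E, P_C) {
  if (is.null(rownames(P_C)) || is.null(rownames(P_E)))
    .stopf("proportion matrices need cell-type rownames")
  if (ncol(P_E) != ncol(P_C))
    .stopf("shape mismatch: %d vs %d mixtures", ncol(P_E), ncol(P_C))
  full <- matrix(0, nrow(P_E), ncol(P_E), dimnames = dimnames(P_E))
  shared <- intersect(rownames(P_E), rownames(P_C))
  full[shared, ] <- P_C[shared, ]
  ok <- !apply(P_C, 2L, anyNA)
  list(P_E = P_E[, ok, drop = FALSE], P_C = full[, ok, drop = FALSE],
       n_used = sum(ok))
}

#' Root-mean-square error between true and estimated proportions
#'
#' Granularities: `per_mixture` returns one RMSE per mixture (root of the
#' mean squared error over cell types); `per_mixture_median` is the median
#' of those (the headline statistic); `per_celltype` is the RMSE over
#' mixtures for each cell type (used by the removal analyses); `pooled`
#' uses all entries at once. Cell types absent from `P_C` are scored as
#' estimated 0; mixtures with degenerate (all-`NA`) estimates are excluded.
#'
#' @param P_E,P_C cell type x mixture proportion matrices (truth,
#'   estimate), with cell-type rownames.
#' @param granularity see above.
#' @return numeric scalar or vector; attribute `n_used` gives the number of
#'   mixtures compared.
#' @export
proportion_rmse <- function(P_E, P_C,
                            granularity = c("per_mixture_median", "per_mixture",
                                            "per_celltype", "pooled")) {
  granularity <- match.arg(granularity)
  al <- .align_props(P_E, P_C)
  err2 <- (al$P_E - al$P_C)^2
  out <- switch(granularity,
    per_mixture = sqrt(colMeans(err2)),
    per_mixture_median = stats::median(sqrt(colMeans(err2))),
    per_celltype = sqrt(rowMeans(err2)),
    pooled = sqrt(mean(err2)))
  attr(out, "n_used") <- al$n_used
  out
}

#' Pearson correlation between true and estimated proportions
#'
#' Same granularities as [proportion_rmse()]; `pooled` correlates all
#' (mixture x cell type) pairs at once, the benchmark's headline
#' correlation. Constant vectors give `NA` (correlation undefined).
#'
#' @inheritParams proportion_rmse
#' @return numeric scalar or vector (possibly `NA`).
#' @export
proportion_pearson <- function(P_E, P_C,
                               granularity = c("pooled", "per_mixture",
                                               "per_mixture_median", "per_celltype")) {
  granularity <- match.arg(granularity)
  al <- .align_props(P_E, P_C)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  out <- switch(granularity,
    pooled = safe_cor(as.vector(al$P_E), as.vector(al$P_C)),
    per_mixture = vapply(seq_len(ncol(al$P_E)), function(j)
      safe_cor(al$P_E[, j], al$P_C[, j]), numeric(1)),
    per_mixture_median = stats::median(vapply(seq_len(ncol(al$P_E)), function(j)
      safe_cor(al$P_E[, j], al$P_C[, j]), numeric(1)), na.rm = TRUE),
    per_celltype = vapply(seq_len(nrow(al$P_E)), function(i)
      safe_cor(al$P_E[i, ], al$P_C[i, ]), numeric(1)))
  attr(out, "n_used") <- al$n_used
  out
}

#' Relative estimation error stratified by expected proportion
#'
#' Summarizes |p_hat - p| / p per bin of the expected proportion p; zero
#' expected proportions are excluded. Smaller expected proportions carry
#' larger relative errors for any fixed absolute error, which is the
#' behaviour this table makes visible.
#'
#' @inheritParams proportion_rmse
#' @param bins increasing break points partitioning (0, 1]; default
#'   deciles.
#' @return data.frame with columns `bin`, `n`, `mean_rel_error`,
#'   `median_rel_error`.
#' @export
relative_error_by_magnitude <- function(P_E, P_C, bins = seq(0, 1, 0.1)) {
  stopifnot(is.numeric(bins), length(bins) >= 2L, !is.unsorted(bins))
  al <- .align_props(P_E, P_C)
  p <- as.vector(al$P_E); ph <- as.vector(al$P_C)
  keep <- p > 0
  p <- p[keep]; ph <- ph[keep]
  rel <- abs(ph - p) / p
  bin <- cut(p, bins, include.lowest = FALSE)
  agg <- split(rel, bin)
  data.frame(bin = names(agg),
             n = vapply(agg, length, integer(1)),
             mean_rel_error = vapply(agg, function(x) if (length(x)) mean(x) else NA_real_, numeric(1)),
             median_rel_error = vapply(agg, function(x) if (length(x)) stats::median(x) else NA_real_, numeric(1)),
             row.names = NULL)
}

#' Missing-cell-type experiment
#'
#' For every victim cell type: restrict to mixtures that actually contain
#' it, deconvolve them once with the full reference and once with the
#' victim's column (and, on the bulk path, its markers) removed, and report
#' the per-cell-type RMSE of both runs plus their fold change. Cell types
#' whose median fold change across the normalization strategies reaches
#' `fold_threshold` are flagged. Pairwise cell-type correlations (markers
#' only and all genes) are attached for interpretation.
#'
#' @param mix a `MixtureSet` built from the test split.
#' @param C full `ReferenceMatrix`.
#' @param markers a `MarkerSet` (strategy `all` in the benchmark).
#' @param methods solver ids.
#' @param normalizations normalization kinds applied to both T and C.
#' @param victims cell types to remove; victims absent from every mixture
#'   are skipped with a reason.
#' @param fold_threshold flagging threshold on the median RMSE fold change.
#' @param transform transformation kind (the benchmark runs this in linear
#'   scale).
#' @return list with `table` (tidy per victim/method/normalization/cell
#'   type), `flags` (per victim/method/cell type median fold change and
#'   flag), `skipped`, `correlations_markers`, `correlations_all`.
#' @export
removal_experiment <- function(mix, C, markers, methods = c("nnls", "svr"),
                               normalizations = c("none", "column", "tmm",
                                                  "median_ratios"),
                               victims = colnames(C), fold_threshold = 2,
                               transform = "linear") {
  stopifnot(inherits(mix, "MixtureSet"))
  if (length(bad <- setdiff(victims, colnames(C))))
    .stopf("victims absent from the reference: %s", paste(bad, collapse = ", "))
  rows <- list(); skipped <- list()
  for (victim in victims) {
    present <- mix$P_E[victim, ] > 0
    if (!any(present)) {
      skipped[[victim]] <- "cell type absent from every mixture"
      next
    }
    sub <- mix
    sub$T <- mix$T[, present, drop = FALSE]
    sub$P_E <- mix$P_E[, present, drop = FALSE]
    sub$provenance <- mix$provenance[present]
    dropped <- drop_cell_type(C, markers, victim)
    for (method in methods) for (nrm in normalizations) {
      base_run <- deconvolve(sub, C, markers, method, transform, nrm, nrm)
      rem_run <- deconvolve(sub, dropped$reference, dropped$markers,
                            method, transform, nrm, nrm)
      if (base_run$skipped || rem_run$skipped) next
      keep_types <- setdiff(rownames(mix$P_E), victim)
      r_full <- proportion_rmse(sub$P_E[keep_types, , drop = FALSE],
                                base_run$P_C[keep_types, , drop = FALSE],
                                "per_celltype")
      r_rem <- proportion_rmse(sub$P_E[keep_types, , drop = FALSE],
                               rem_run$P_C, "per_celltype")
      rows[[length(rows) + 1L]] <- data.frame(
        victim = victim, method = method, normalization = nrm,
        cell_type = keep_types,
        rmse_full = as.numeric(r_full), rmse_removed = as.numeric(r_rem),
        fold_change = as.numeric(r_rem) / pmax(as.numeric(r_full), 1e-12),
        n_mixtures = sum(present), row.names = NULL)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(victim = character(), method = character(),
               normalization = character(), cell_type = character(),
               rmse_full = numeric(), rmse_removed = numeric(),
               fold_change = numeric(), n_mixtures = integer())
  flags <- NULL
  if (nrow(table)) {
    sp <- split(table, list(table$victim, table$method, table$cell_type),
                drop = TRUE)
    flags <- do.call(rbind, lapply(sp, function(d) data.frame(
      victim = d$victim[1L], method = d$method[1L], cell_type = d$cell_type[1L],
      median_fold_change = stats::median(d$fold_change),
      flagged = stats::median(d$fold_change) >= fold_threshold,
      row.names = NULL)))
    rownames(flags) <- NULL
  }
  list(table = table, flags = flags, skipped = skipped,
       correlations_markers = celltype_correlations(C, markers),
       correlations_all = celltype_correlations(C))
}

#' Full benchmark configuration
#'
#' Collects every knob of the pipeline with the benchmark's defaults: QC at
#' 3 MADs, 5% prevalence, 50 cells per type; 50:50 split; fold-change
#' threshold 2 at BH 0.05; 1000 mixtures of pool size 100 with 2-5 types on
#' the 0.05 grid. One master seed deterministically derives per-stage
#' seeds.
#'
#' @param preset synthetic preset name, or `NULL` when `paths` is given.
#' @param paths optional list `(path =, format =)` for on-disk input.
#' @param qc named list of [qc_filter()] arguments to override.
#' @param split_mode `"by_cell"` or `"by_donor"`.
#' @param fc_threshold,alpha marker thresholds (`NULL`: use the preset's).
#' @param strategies marker strategies to run.
#' @param n_mixtures,pool_size,k_range,grid_step composition rules (`NULL`
#'   entries fall back to the preset's grid).
#' @param transforms,scalingT,scalingC,methods grid axes.
#' @param seed master seed.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(preset = "pancreas_like", paths = NULL,
                            qc = list(), split_mode = "by_cell",
                            fc_threshold = NULL, alpha = 0.05,
                            strategies = "all",
                            n_mixtures = 1000L, pool_size = 100L,
                            k_range = NULL, grid_step = NULL,
                            transforms = "linear", scalingT = "column",
                            scalingC = "column", methods = "nnls",
                            seed = 1L) {
  if (!length(methods)) .stopf("empty method list")
  structure(list(preset = preset, paths = paths, qc = qc,
                 split_mode = split_mode, fc_threshold = fc_threshold,
                 alpha = alpha, strategies = strategies,
                 n_mixtures = as.integer(n_mixtures),
                 pool_size = as.integer(pool_size),
                 k_range = k_range, grid_step = grid_step,
                 transforms = transforms, scalingT = scalingT,
                 scalingC = scalingC, methods = methods,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full benchmark grid
#'
#' Executes QC, split, reference building, marker selection, pseudo-bulk
#' generation and the (transform x scalingT x scalingC x method x marker
#' strategy) grid, scoring every combination by RMSE and Pearson
#' correlation. Skipped (incompatible) combinations are recorded with
#' their reason.
#'
#' @param config a [pipeline_config()].
#' @param data optional `CellExpressionMatrix` to use instead of loading or
#'   simulating (e.g. an already generated fixture).
#' @return an `EvaluationReport` data.frame with one row per combination
#'   (rmse_median, rmse_pooled, pearson_pooled, pearson_median, n_mixtures,
#'   skip reason); attributes `manifest` (effective config), `mixtures`,
#'   `reference`, `markers` expose the intermediates.
#' @export
run_benchmark <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(s) stage_seed(config$seed, s)
  x <- data %||% (if (!is.null(config$paths))
    do.call(read_counts, config$paths)
  else make_benchmark_fixture(config$preset, seed = stage("simulate")))
  preset_info <- attr(x, "preset")

  qc <- do.call(qc_filter, c(list(x), config$qc))
  sp <- split_train_test(qc$data, config$split_mode, seed = stage("split"))
  C <- build_reference(sp$train)
  fc <- config$fc_threshold %||% preset_info$fc_threshold %||% 2
  stats <- rank_genes(sp$train, fc_threshold = fc, alpha = config$alpha)
  marker_sets <- lapply(stats::setNames(config$strategies, config$strategies),
                        function(s) select_markers(stats, s, seed = stage("markers")))
  rules <- composition_rules(
    n_mixtures = config$n_mixtures, pool_size = config$pool_size,
    k_range = config$k_range %||% preset_info$k_range %||% c(2L, 5L),
    grid_step = config$grid_step %||% preset_info$grid_step %||% 0.05,
    seed = stage("mixtures"))
  mix <- generate_mixtures(sp$test, rules)

  rows <- list()
  for (tr in config$transforms) for (sT in config$scalingT)
    for (sC in config$scalingC) for (met in config$methods)
      for (st in config$strategies) {
        res <- deconvolve(mix, C, marker_sets[[st]], met, tr, sT, sC)
        rows[[length(rows) + 1L]] <- if (res$skipped) data.frame(
          method = met, transform = tr, scalingT = sT, scalingC = sC,
          marker_strategy = st, pool_size = config$pool_size,
          removed_cell_type = "none", rmse_median = NA_real_,
          rmse_pooled = NA_real_, pearson_pooled = NA_real_,
          pearson_median = NA_real_, n_mixtures = 0L,
          skipped = TRUE, reason = res$reason)
        else data.frame(
          method = met, transform = tr, scalingT = sT, scalingC = sC,
          marker_strategy = st, pool_size = config$pool_size,
          removed_cell_type = "none",
          rmse_median = as.numeric(proportion_rmse(mix$P_E, res$P_C)),
          rmse_pooled = as.numeric(proportion_rmse(mix$P_E, res$P_C, "pooled")),
          pearson_pooled = as.numeric(proportion_pearson(mix$P_E, res$P_C)),
          pearson_median = as.numeric(proportion_pearson(mix$P_E, res$P_C,
                                                         "per_mixture_median")),
          n_mixtures = attr(proportion_rmse(mix$P_E, res$P_C), "n_used"),
          skipped = FALSE, reason = "")
      }
  report <- do.call(rbind, rows)
  class(report) <- c("EvaluationReport", "data.frame")
  attr(report, "manifest") <- unclass(config)
  attr(report, "mixtures") <- mix
  attr(report, "reference") <- C
  attr(report, "markers") <- marker_sets
  attr(report, "qc_report") <- qc$report
  report
}
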