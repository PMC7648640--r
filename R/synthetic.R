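#' Specification of a synthetic scRNA-seq dataset
#'
#' Describes the generative model used by [generate_dataset()]: counts are
#' negative-binomial (variance mu + alpha mu^2) around per-type mean
#' profiles. A gene's relative expression is a shared lognormal baseline
#' times a type-specific lognormal deviation; `correlation_pairs` set the
#' correlation of those deviations for chosen type pairs, so configured
#' similarity is monotone in the expected expression-profile correlation.
#' Marker genes (disjoint blocks per type) have no type deviation but are
#' multiplied by `marker_fold_change` in their own type, so they are
#' over-expressed relative to the second-highest type by the configured
#' fold. Donors act as gene-wise multiplicative lognormal effects; library
#' sizes are lognormal per cell.
#'
#' @param n_genes number of genes.
#' @param cell_types data.frame with columns `name`, `n_cells`,
#'   `mean_library_size`.
#' @param n_donors number of donors (cells assigned round-robin).
#' @param marker_frac fraction of genes planted as markers per type
#'   (`marker_frac * n_types` must be <= 1).
#' @param marker_fold_change multiplicative marker effect, >= 1.
#' @param nb_dispersion NB dispersion alpha >= 0 (0 = Poisson).
#' @param donor_effect_sd log-scale sd of gene-wise donor effects.
#' @param correlation_pairs list of `list(a, b, similarity)` with similarity
#'   in \[0, 1\].
#' @param seed integer seed; fixing it fixes every draw.
#' @param base_sdlog,type_sdlog log-scale sds of the shared baseline and the
#'   type-specific deviations; their ratio sets the baseline between-type
#'   profile correlation.
#' @param lib_sdlog log-scale sd of per-cell library sizes (0 = constant).
#' @return a `SyntheticSpec` object.
#' @export
synthetic_spec <- function(n_genes, cell_types, n_donors = 2L,
                           marker_frac = 0.04, marker_fold_change = 4,
                           nb_dispersion = 0.2, donor_effect_sd = 0.15,
                           correlation_pairs = list(), seed = 1L,
                           base_sdlog = 0.4, type_sdlog = 1.1,
                           lib_sdlog = 0.25) {
  stopifnot(.is_count(n_genes), n_genes >= 1,
            is.data.frame(cell_types),
            all(c("name", "n_cells", "mean_library_size") %in% names(cell_types)),
            .is_count(n_donors), n_donors >= 1,
            marker_frac >= 0, marker_fold_change >= 1,
            nb_dispersion >= 0, donor_effect_sd >= 0, lib_sdlog >= 0)
  if (anyDuplicated(cell_types$name)) .stopf("cell type names must be unique")
  if (marker_frac * nrow(cell_types) > 1)
    .stopf("infeasible spec: marker_frac (%.3f) x %d types exceeds 1",
           marker_frac, nrow(cell_types))
  for (p in correlation_pairs) {
    if (!all(c(p[[1]], p[[2]]) %in% cell_types$name))
      .stopf("correlation pair names unknown: %s, %s", p[[1]], p[[2]])
    if (p[[3]] < 0 || p[[3]] > 1) .stopf("similarity must lie in [0, 1]")
  }
  structure(list(n_genes = as.integer(n_genes), cell_types = cell_types,
                 n_donors = as.integer(n_donors), marker_frac = marker_frac,
                 marker_fold_change = marker_fold_change,
                 nb_dispersion = nb_dispersion, donor_effect_sd = donor_effect_sd,
                 correlation_pairs = correlation_pairs, seed = as.integer(seed),
                 base_sdlog = base_sdlog, type_sdlog = type_sdlog,
                 lib_sdlog = lib_sdlog),
            class = "SyntheticSpec")
}

#' Generate a synthetic labelled count matrix
#'
#' @param spec a [synthetic_spec()].
#' @return a `CellExpressionMatrix` with attributes `marker_truth` (list of
#'   planted marker gene ids per type) and `synthetic_spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, .generate_dataset_impl(spec))
}

.generate_dataset_impl <- function(spec) {
  types <- spec$cell_types$name
  K <- length(types)
  G <- spec$n_genes
  gid <- sprintf("gene%05d", seq_len(G))
  donors <- sprintf("donor%d", seq_len(spec$n_donors))

  ## planted markers: disjoint random blocks per type
  n_mark <- floor(spec$marker_frac * G)
  marker_truth <- stats::setNames(vector("list", K), types)
  pool <- sample.int(G)
  is_marker <- rep(FALSE, G)
  for (k in seq_len(K)) {
    idx <- pool[seq.int((k - 1L) * n_mark + 1L, length.out = n_mark)]
    marker_truth[[k]] <- sort(gid[idx])
    is_marker[idx] <- TRUE
  }

  ## shared baseline and correlated type deviations (log scale)
  base <- stats::rnorm(G, 0, spec$base_sdlog)
  z <- matrix(stats::rnorm(G * K), G, K, dimnames = list(NULL, types))
  for (p in spec$correlation_pairs) {
    a <- p[[1]]; b <- p[[2]]; s <- p[[3]]
    z[, b] <- s * z[, a] + sqrt(1 - s^2) * z[, b]
  }
  logm <- base + spec$type_sdlog * z       # G x K
  logm[is_marker, ] <- base[is_marker]     # markers: no type deviation ...
  for (k in seq_len(K)) {                  # ... except the owning type's fold
    idx <- match(marker_truth[[k]], gid)
    logm[idx, k] <- logm[idx, k] + log(spec$marker_fold_change)
  }
  m <- exp(logm)

  ## donor effects, gene-wise multiplicative
  dfac <- matrix(exp(stats::rnorm(G * spec$n_donors, 0, spec$donor_effect_sd)),
                 G, spec$n_donors, dimnames = list(NULL, donors))

  n_cells <- sum(spec$cell_types$n_cells)
  counts <- matrix(0, G, n_cells)
  ct <- character(n_cells); dn <- character(n_cells)
  size <- if (spec$nb_dispersion > 0) 1 / spec$nb_dispersion else Inf
  col <- 0L
  for (k in seq_len(K)) {
    nk <- spec$cell_types$n_cells[k]
    mls <- spec$cell_types$mean_library_size[k]
    cell_donor <- rep(seq_len(spec$n_donors), length.out = nk)
    libs <- if (spec$lib_sdlog > 0)
      stats::rlnorm(nk, log(mls) - spec$lib_sdlog^2 / 2, spec$lib_sdlog)
    else rep(mls, nk)
    for (j in seq_len(nk)) {
      col <- col + 1L
      w <- m[, k] * dfac[, cell_donor[j]]
      mu <- w / sum(w) * libs[j]
      counts[, col] <- if (is.finite(size)) stats::rnbinom(G, mu = mu, size = size)
                       else stats::rpois(G, mu)
      ct[col] <- types[k]; dn[col] <- donors[cell_donor[j]]
    }
  }
  rownames(counts) <- gid
  colnames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  out <- cell_expression_matrix(counts, ct, dn)
  attr(out, "marker_truth") <- marker_truth
  attr(out, "synthetic_spec") <- spec
  out
}

#' Built-in benchmark fixtures
#'
#' Small synthetic datasets emulating the benchmark's tissue scenarios:
#' `pancreas_like` (5 well-separated endocrine/exocrine-like types, the
#' scale used by the headline acceptance runs), `pbmc_like` (6 types
#' including one highly similar monocyte/dendritic-like pair, configured
#' similarity 0.85, and one type unrelated to all others, to exercise the
#' missing-cell-type hypotheses) and `kidney_like` (8 types, the maximum
#' used in the benchmark). Each fixture appends all-zero genes and a few
#' library-size outlier cells so that [qc_filter()] has non-trivial work.
#'
#' @param preset `"pancreas_like"`, `"pbmc_like"` or `"kidney_like"`.
#' @param seed integer seed; same seed, byte-identical dataset.
#' @return a `CellExpressionMatrix` with attributes `marker_truth`,
#'   `synthetic_spec`, and `preset` (a list with the preset's recommended
#'   `fc_threshold` and composition-grid settings).
#' @export
make_benchmark_fixture <- function(preset = c("pancreas_like", "pbmc_like", "kidney_like"),
                                   seed = 1L) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    pancreas_like = list(
      cell_types = data.frame(
        name = c("alpha", "beta", "gamma", "delta", "acinar"),
        n_cells = 200L,
        mean_library_size = c(3900, 3700, 3850, 4000, 4100)),
      n_genes = 1500L, n_donors = 4L, fc_threshold = 2,
      k_range = c(2L, 5L), grid_step = 0.05, pairs = list()),
    pbmc_like = list(
      cell_types = data.frame(
        name = c("Tcell", "Bcell", "NK", "CD14mono", "dendritic", "megakaryo"),
        n_cells = 160L,
        mean_library_size = c(1150, 1100, 1180, 1220, 1200, 1080)),
      n_genes = 1200L, n_donors = 2L, fc_threshold = 1.5,
      k_range = c(2L, 5L),
      grid_step = 0.05,
      pairs = list(list("CD14mono", "dendritic", 0.85))),
    kidney_like = list(
      cell_types = data.frame(
        name = sprintf("ktype%d", 1:8),
        n_cells = 150L,
        mean_library_size = round(seq(850, 950, length.out = 8))),
      n_genes = 1500L, n_donors = 2L, fc_threshold = 1.8,
      k_range = c(2L, 8L), grid_step = 0.01, pairs = list()))
  spec <- synthetic_spec(
    n_genes = cfg$n_genes, cell_types = cfg$cell_types,
    n_donors = cfg$n_donors, marker_frac = 0.04, marker_fold_change = 4,
    nb_dispersion = 0.2, donor_effect_sd = 0.15,
    correlation_pairs = cfg$pairs, seed = seed)
  x <- generate_dataset(spec)
  x <- with_seed(stage_seed(seed, paste0("fixture_", preset)), {
    ## QC fodder: all-zero genes plus library-size outlier cells
    zg <- matrix(0, 20L, ncol(x$counts),
                 dimnames = list(sprintf("zerogene%03d", 1:20), cell_ids(x)))
    counts <- rbind(x$counts, zg)
    out_idx <- sample(ncol(counts), 8L)
    outliers <- counts[, out_idx, drop = FALSE] * 10
    colnames(outliers) <- sprintf("outliercell%02d", seq_along(out_idx))
    counts <- cbind(counts, outliers)
    y <- cell_expression_matrix(counts,
                                c(x$cell_type, x$cell_type[out_idx]),
                                c(x$donor, x$donor[out_idx]))
    attr(y, "marker_truth") <- attr(x, "marker_truth")
    attr(y, "synthetic_spec") <- attr(x, "synthetic_spec")
    y
  })
  attr(x, "preset") <- list(name = preset, fc_threshold = cfg$fc_threshold,
                            k_range = cfg$k_range, grid_step = cfg$grid_step)
  x
}
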