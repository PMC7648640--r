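#' Composition rules for pseudo-bulk generation
#'
#' The benchmark's defaults: 1000 mixtures of pool size 100, each containing
#' between 2 and 5 cell types, with proportions drawn uniformly from the
#' grid of multiples of 0.05 on \[0.05, 1\] summing to 1. The kidney-style
#' preset widens the range to 2-8 types on a 0.01 grid.
#'
#' @param n_mixtures number of pseudo-bulk mixtures.
#' @param pool_size cells summed per mixture.
#' @param k_range integer interval (min, max) of cell types per mixture.
#' @param grid_step proportion grid step; the grid minimum equals the step.
#' @param seed integer seed.
#' @param max_rejections bound on composition redraws when a draw requires
#'   more cells of a type than are available.
#' @return a `CompositionRules` object.
#' @export
composition_rules <- function(n_mixtures = 1000L, pool_size = 100L,
                              k_range = c(2L, 5L), grid_step = 0.05,
                              seed = 1L, max_rejections = 1000L) {
  stopifnot(.is_count(n_mixtures), n_mixtures >= 1,
            .is_count(pool_size), pool_size >= 1,
            length(k_range) == 2L, k_range[1L] >= 1L, k_range[2L] >= k_range[1L],
            grid_step > 0, grid_step <= 1)
  units <- 1 / grid_step
  if (abs(units - round(units)) > 1e-9)
    .stopf("grid_step must divide 1 exactly (got %g)", grid_step)
  structure(list(n_mixtures = as.integer(n_mixtures),
                 pool_size = as.integer(pool_size),
                 k_range = as.integer(k_range), grid_step = grid_step,
                 seed = as.integer(seed),
                 max_rejections = as.integer(max_rejections)),
            class = "CompositionRules")
}

#' Enumerate all grid compositions of k parts summing to one
#'
#' All length-`k` tuples of multiples of `grid_step`, each at least
#' `grid_step`, summing exactly to 1 (in integer grid units). With k = 2 and
#' step 0.05 there are 19 compositions (0.05/0.95 ... 0.95/0.05).
#'
#' @param k number of parts.
#' @param grid_step grid step (the minimum part).
#' @return matrix with `k` columns, one composition per row.
#' @export
enumerate_grid_compositions <- function(k, grid_step = 0.05) {
  stopifnot(.is_count(k), k >= 1)
  N <- round(1 / grid_step)
  if (k > N) .stopf("no composition: %d parts cannot each get >= %g", k, grid_step)
  rec <- function(n, parts) {
    if (parts == 1L) return(matrix(n, 1L, 1L))
    do.call(rbind, lapply(seq.int(1L, n - parts + 1L), function(a)
      cbind(a, rec(n - a, parts - 1L))))
  }
  unname(rec(N, as.integer(k)) * grid_step)
}

## number of compositions of n units into k parts, each >= 1 (stars & bars);
## doubles are exact well past the kidney-scale C(99, 7)
.n_compositions <- function(n, k) choose(n - 1, k - 1)

## draw one composition uniformly from the grid simplex by sampling each
## part from its exact marginal (counting completions), avoiding both full
## enumeration and sequential-draw bias
.sample_composition <- function(k, grid_step) {
  N <- as.integer(round(1 / grid_step))
  out <- integer(k)
  left <- N
  for (i in seq_len(k - 1L)) {
    parts_left <- k - i
    vals <- seq.int(1L, left - parts_left)
    wt <- .n_compositions(left - vals, parts_left)
    out[i] <- vals[sample.int(length(vals), 1L, prob = wt)]
    left <- left - out[i]
  }
  out[k] <- left
  out * grid_step
}

#' Generate pseudo-bulk mixtures with known composition
#'
#' For each mixture: the number of cell types k is drawn uniformly from
#' `k_range`, k distinct types are drawn uniformly, a composition is drawn
#' uniformly from the grid simplex and converted to cell counts
#' (largest-remainder rounding; exact for pool sizes divisible by the grid
#' unit). If some type lacks enough cells the composition (only) is
#' redrawn. Cells are then sampled without replacement within the mixture
#' (reuse across mixtures is allowed) and their raw counts summed.
#'
#' @param test a `CellExpressionMatrix` (the testing split).
#' @param rules a [composition_rules()].
#' @return a `MixtureSet`: list with `T` (gene x mixture summed counts),
#'   `P_E` (cell type x mixture ground-truth proportions), `provenance`
#'   (list of selected cell ids per mixture) and `rules`.
#' @export
generate_mixtures <- function(test, rules = composition_rules()) {
  stopifnot(inherits(test, "CellExpressionMatrix"),
            inherits(rules, "CompositionRules"))
  types <- sort(unique(test$cell_type))
  if (rules$k_range[2L] > length(types))
    .stopf("k_range max (%d) exceeds the %d available cell types",
           rules$k_range[2L], length(types))
  cells_by_type <- lapply(stats::setNames(types, types),
                          function(k) which(test$cell_type == k))
  avail <- lengths(cells_by_type)
  if (any(avail < 1L)) .stopf("every cell type needs >= 1 test cell")

  G <- nrow(test$counts)
  M <- rules$n_mixtures
  T_mat <- matrix(0, G, M, dimnames = list(gene_ids(test),
                                           sprintf("mix%04d", seq_len(M))))
  P_E <- matrix(0, length(types), M, dimnames = list(types, colnames(T_mat)))
  prov <- vector("list", M)

  with_seed(rules$seed, {
    for (m in seq_len(M)) {
      k <- sample(seq.int(rules$k_range[1L], rules$k_range[2L]), 1L)
      chosen <- sample(types, k)
      n_cells <- NULL
      for (try in seq_len(rules$max_rejections)) {
        p <- .sample_composition(k, rules$grid_step)
        n_cells <- .largest_remainder(p * rules$pool_size)
        if (all(n_cells <= avail[chosen])) break
        n_cells <- NULL
      }
      if (is.null(n_cells)) {
        short <- chosen[which.max(p * rules$pool_size - avail[chosen])]
        .stopf("no feasible composition for mixture %d after %d redraws (limiting cell type: %s)",
               m, rules$max_rejections, short)
      }
      sel <- unlist(lapply(seq_len(k), function(i)
        cells_by_type[[chosen[i]]][sample.int(avail[chosen[i]], n_cells[i])]),
        use.names = FALSE)
      T_mat[, m] <- rowSums(test$counts[, sel, drop = FALSE])
      P_E[chosen, m] <- p
      prov[[m]] <- cell_ids(test)[sel]
    }
  })
  structure(list(T = T_mat, P_E = P_E, provenance = prov, rules = rules),
            class = "MixtureSet")
}

## round real cell counts to integers preserving the total
## (largest-remainder a.k.a. Hamilton; ties broken by index)
.largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    extra <- order(-(x - fl), seq_along(x))[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' @export
print.MixtureSet <- function(x, ...) {
  cat(sprintf("MixtureSet: %d genes x %d mixtures, pool size %d, %d cell types\n",
              nrow(x$T), ncol(x$T), x$rules$pool_size, nrow(x$P_E)))
  invisible(x)
}

#' Write a MixtureSet as plain-text tables
#'
#' `T.tsv` (counts), `P_E.tsv` (ground-truth proportions) and
#' `provenance.tsv` (mixture, cell id) under `dir`.
#'
#' @param mix a `MixtureSet`.
#' @param dir output directory.
#' @export
write_mixture_set <- function(mix, dir) {
  stopifnot(inherits(mix, "MixtureSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::data.table(gene = rownames(mix$T), mix$T),
                     file.path(dir, "T.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(cell_type = rownames(mix$P_E), mix$P_E),
                     file.path(dir, "P_E.tsv"), sep = "\t")
  prov <- data.table::data.table(
    mixture = rep(colnames(mix$T), lengths(mix$provenance)),
    cell_id = unlist(mix$provenance, use.names = FALSE))
  data.table::fwrite(prov, file.path(dir, "provenance.tsv"), sep = "\t")
  invisible(dir)
}
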