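rand_props <- function(seed, k = 4, m = 12) {
  set.seed(seed)
  P <- matrix(rexp(k * m), k, m,
              dimnames = list(paste0("t", seq_len(k)), paste0("m", seq_len(m))))
  sweep(P, 2, colSums(P), "/")
}

test_that("RMSE follows its closed forms", {
  P <- rand_props(1)
  z <- proportion_rmse(P, P)
  expect_equal(as.numeric(z), 0)
  for (g in c("per_mixture", "per_celltype", "pooled"))
    expect_true(all(proportion_rmse(P, P, g) == 0))
  P_E <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("a", "b"), "m1"))
  P_C <- matrix(c(0.6, 0.4), 2, 1, dimnames = list(c("a", "b"), "m1"))
  expect_equal(as.numeric(proportion_rmse(P_E, P_C, "per_mixture")), 0.1)
  ## homogeneity: doubling the error doubles the RMSE
  Q <- rand_props(2)
  E <- (Q - P) / 2
  r1 <- proportion_rmse(P, P + E, "pooled")
  r2 <- proportion_rmse(P, P + 2 * E, "pooled")
  expect_equal(as.numeric(r2), 2 * as.numeric(r1), tolerance = 1e-12)
  expect_error(proportion_rmse(P, P[, 1:3]), "mismatch")
})

test_that("RMSE and Pearson match brute-force recomputation to 1e-12", {
  for (seed in 1:20) {
    P_E <- rand_props(seed)
    P_C <- rand_props(seed + 100)
    ## independent recomputation with explicit loops
    k <- nrow(P_E); m <- ncol(P_E)
    per_mix <- vapply(seq_len(m), function(j)
      sqrt(sum((P_E[, j] - P_C[, j])^2) / k), numeric(1))
    expect_equal(as.numeric(proportion_rmse(P_E, P_C, "per_mixture")), per_mix,
                 tolerance = 1e-12)
    expect_equal(as.numeric(proportion_rmse(P_E, P_C)), median(per_mix),
                 tolerance = 1e-12)
    pool <- 0
    for (i in seq_len(k)) for (j in seq_len(m))
      pool <- pool + (P_E[i, j] - P_C[i, j])^2
    expect_equal(as.numeric(proportion_rmse(P_E, P_C, "pooled")),
                 sqrt(pool / (k * m)), tolerance = 1e-12)
    x <- as.vector(P_E); y <- as.vector(P_C)
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(as.numeric(proportion_pearson(P_E, P_C)), r, tolerance = 1e-12)
  }
})

test_that("Pearson is blind to affine distortion (the correlation caveat)", {
  P <- rand_props(3)
  Q <- 0.5 * P + 0.1
  expect_equal(as.numeric(proportion_pearson(P, Q)), 1, tolerance = 1e-12)
  expect_gt(as.numeric(proportion_rmse(P, Q, "pooled")), 0)
  ## constant estimates have undefined correlation
  Flat <- P; Flat[] <- 1 / nrow(P)
  expect_true(is.na(proportion_pearson(P, Flat)))
})

test_that("missing cell types in the estimate are scored as zero", {
  P_E <- rand_props(4)
  P_C <- P_E[-1, , drop = FALSE]
  expect_equal(as.numeric(proportion_rmse(P_E, P_C, "per_celltype"))[1],
               sqrt(mean(P_E[1, ]^2)))
  ## degenerate (NA) mixtures are excluded and counted
  P_C2 <- P_E; P_C2[, 2] <- NA
  r <- proportion_rmse(P_E, P_C2)
  expect_equal(attr(r, "n_used"), ncol(P_E) - 1L)
})

test_that("relative error decreases with expected proportion at fixed absolute error", {
  P <- rand_props(5, k = 5, m = 200)
  Q <- pmin(pmax(P + 0.05, 0), 1)   # constant +0.05 absolute error
  tab <- relative_error_by_magnitude(P, Q, bins = c(0, 0.2, 0.4, 0.6, 0.8, 1))
  got <- tab$mean_rel_error[!is.na(tab$mean_rel_error)]
  expect_true(all(diff(got) < 0))
  perfect <- relative_error_by_magnitude(P, P)
  expect_true(all(perfect$mean_rel_error[perfect$n > 0] == 0))
  expect_equal(nrow(relative_error_by_magnitude(P, Q, bins = c(0, 0.5, 1))), 2)
})

test_that("removal experiment reports per-type baselines faithfully", {
  pp <- pancreas_pipeline()
  mix <- generate_mixtures(pp$test, composition_rules(n_mixtures = 60, seed = 5))
  rem <- removal_experiment(mix, pp$C, pp$markers, methods = "nnls",
                            normalizations = "column", victims = "alpha")
  tb <- rem$table
  expect_true(all(tb$victim == "alpha"))
  expect_false("alpha" %in% tb$cell_type)
  ## baseline column matches an independent deconvolution of the same subset
  present <- mix$P_E["alpha", ] > 0
  sub <- mix
  sub$T <- mix$T[, present]; sub$P_E <- mix$P_E[, present]
  sub$provenance <- mix$provenance[present]
  base <- deconvolve(sub, pp$C, pp$markers, "nnls", "linear", "column", "column")
  keep <- setdiff(rownames(mix$P_E), "alpha")
  want <- proportion_rmse(sub$P_E[keep, ], base$P_C[keep, ], "per_celltype")
  expect_equal(tb$rmse_full, unname(as.numeric(want)), tolerance = 1e-12)
  expect_true(all(c("correlations_markers", "correlations_all") %in% names(rem)))
  ## a victim in no mixture is skipped with a reason
  mix0 <- mix
  mix0$P_E["gamma", ] <- 0
  rem0 <- removal_experiment(mix0, pp$C, pp$markers, methods = "nnls",
                             normalizations = "column", victims = "gamma")
  expect_match(rem0$skipped$gamma, "absent")
  expect_error(removal_experiment(mix, pp$C, pp$markers, victims = "nope"),
               "absent from the reference")
})

test_that("run_benchmark executes the grid and is reproducible", {
  cfg <- pipeline_config(preset = "pancreas_like", n_mixtures = 40,
                         transforms = c("linear", "log"),
                         methods = "nnls", seed = 5)
  rep1 <- run_benchmark(cfg)
  expect_s3_class(rep1, "EvaluationReport")
  expect_equal(nrow(rep1), 2)
  lin <- rep1$rmse_median[rep1$transform == "linear"]
  lg <- rep1$rmse_median[rep1$transform == "log"]
  expect_lt(lin, lg)
  rep2 <- run_benchmark(cfg)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
  expect_error(pipeline_config(methods = character(0)), "empty method list")
  ## skipped combinations are carried through with reasons
  cfg2 <- pipeline_config(preset = "pancreas_like", n_mixtures = 10,
                          transforms = "log", scalingT = "median_ratios",
                          methods = "nnls", seed = 5)
  rep3 <- run_benchmark(cfg2)
  expect_true(all(rep3$skipped))
  expect_match(rep3$reason[1], "linear")
})
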