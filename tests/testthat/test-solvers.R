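test_that("noiseless mixtures are recovered at each solver's tolerance", {
  fx <- solver_fixture()
  C <- fx$C; t <- fx$t; p <- fx$p
  err <- function(est) max(abs(postprocess_proportions(est) - p))
  expect_lt(err(solve_ols(C, t)), 1e-8)
  expect_lt(err(solve_nnls(C, t)), 1e-8)
  expect_lt(err(solve_qp(C, t)), 1e-8)
  expect_lt(err(solve_rlr(C, t)), 1e-6)
  expect_lt(err(solve_dwls(C, t)), 1e-4)
  expect_lt(err(solve_svr(C, t)), 0.02)
})

test_that("degenerate directions behave as documented", {
  fx <- solver_fixture()
  C <- fx$C
  expect_equal(unname(postprocess_proportions(solve_ols(C, C[, 2]))),
               c(0, 1, 0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(solve_ols(C, numeric(nrow(C)))), rep(0, 5),
               tolerance = 1e-12)
  ## duplicated reference column: solvers terminate and flag the deficiency
  C2 <- cbind(C, dup = C[, 1])
  expect_warning(solve_ols(C2, fx$t), "rank")
  expect_silent(solve_nnls(C2, fx$t))
  expect_length(solve_qp(C2, fx$t), 6)
})

test_that("NNLS matches brute-force active-set enumeration on a toy", {
  set.seed(10)
  for (i in 1:20) {
    C <- matrix(rnorm(12, 5, 2), 4, 3)
    t <- rnorm(4, 3, 2)
    x <- solve_nnls(C, t)
    ## brute force: best non-negative solution over all support sets
    best <- rep(0, 3); best_rss <- sum(t^2)
    for (S in 1:7) {
      idx <- which(bitwAnd(S, c(1L, 2L, 4L)) > 0)
      b <- qr.coef(qr(C[, idx, drop = FALSE]), t)
      if (any(is.na(b)) || any(b < 0)) next
      full <- rep(0, 3); full[idx] <- b
      rss <- sum((t - C %*% full)^2)
      if (rss < best_rss - 1e-12) { best <- full; best_rss <- rss }
    }
    expect_equal(x, best, tolerance = 1e-8)
    expect_true(all(x >= 0))
    expect_gte(sum((t - C %*% x)^2) + 1e-12, sum(qr.resid(qr(C), t)^2))
  }
})

test_that("simplex QP satisfies its constraints and the quadprog oracle", {
  set.seed(11)
  for (i in 1:20) {
    C <- matrix(rexp(60, 1 / 10), 20, 3)
    t <- rexp(20, 1 / 10)
    x <- solve_qp(C, t)
    expect_lt(abs(sum(x) - 1), 1e-10)
    expect_true(all(x >= -1e-12))
    oracle <- quadprog::solve.QP(
      Dmat = crossprod(C), dvec = crossprod(C, t),
      Amat = cbind(rep(1, 3), diag(3)), bvec = c(1, 0, 0, 0), meq = 1)$solution
    expect_equal(x, pmax(oracle, 0), tolerance = 1e-6)
  }
  ## symmetry: the average of two reference columns splits evenly
  fx <- solver_fixture()
  x <- solve_qp(fx$C, (fx$C[, 1] + fx$C[, 2]) / 2)
  expect_equal(unname(x), c(0.5, 0.5, 0, 0, 0), tolerance = 1e-8)
})

test_that("Huber IRLS resists outliers and collapses to OLS in the limit", {
  set.seed(12)
  wins <- 0
  for (i in 1:200) {
    C <- matrix(rexp(150 * 4, 1 / 40), 150, 4)
    p <- c(0.3, 0.3, 0.2, 0.2)
    t <- drop(C %*% p)
    out <- sample(150, 3)              # 2% corrupted genes
    t[out] <- t[out] * 20
    e_rlr <- sqrt(sum((solve_rlr(C, t) - p)^2))
    e_ols <- sqrt(sum((solve_ols(C, t) - p)^2))
    wins <- wins + (e_rlr < e_ols)
  }
  expect_gte(wins, 190)                # >= 95% of 200 seeded trials

  fx <- solver_fixture()
  t_noisy <- fx$t * (1 + rnorm(length(fx$t), 0, 0.1))
  expect_equal(solve_rlr(fx$C, t_noisy, tuning = 1e12),
               solve_ols(fx$C, t_noisy), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("penalized solvers: OLS limit, ridge closed form, glmnet oracle", {
  fx <- solver_fixture(genes = 100, k = 4)
  C <- fx$C; t <- fx$t + rnorm(100, 0, 2)
  for (pen in c("ridge", "lasso")) {
    expect_equal(solve_penalized(C, t, pen, lambda_grid = 1e-10),
                 solve_ols(C, t), tolerance = 1e-6, ignore_attr = TRUE)
  }
  lam <- 0.7
  direct <- drop(solve(crossprod(C) / 100 + diag(lam, 4), crossprod(C, t) / 100))
  expect_equal(solve_penalized(C, t, "ridge", lambda_grid = lam), direct,
               tolerance = 1e-10, ignore_attr = TRUE)
  ## coordinate descent against glmnet at a fixed lambda
  g <- glmnet::glmnet(C, t, alpha = 1, lambda = lam, intercept = FALSE,
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(solve_penalized(C, t, "lasso", lambda_grid = lam),
               as.numeric(g$beta), tolerance = 1e-6, ignore_attr = TRUE)
  ## an overwhelming penalty zeroes everything -> degenerate postprocessing
  z <- solve_penalized(C, t, "lasso", lambda_grid = 1e9)
  expect_true(all(z == 0))
  expect_true(isTRUE(attr(postprocess_proportions(z), "degenerate")))
  expect_error(solve_penalized(C, t, "lasso", lambda_grid = numeric(0)), "empty")
})

test_that("nu-SVR selects the best-fitting nu and ignores gene order", {
  fx <- solver_fixture()
  t <- fx$t * (1 + rnorm(length(fx$t), 0, 0.05))
  est <- solve_svr(fx$C, t)
  fits <- attr(est, "fit_rmse")
  expect_equal(attr(est, "nu"), as.numeric(names(which.min(fits))))
  perm <- sample(nrow(fx$C))
  est2 <- solve_svr(fx$C[perm, ], t[perm])
  expect_equal(as.numeric(est), as.numeric(est2), tolerance = 1e-4)
})

test_that("DWLS helps rare cell types and collapses to NNLS when flat", {
  set.seed(14)
  wins <- 0
  for (i in 1:200) {
    C <- matrix(rexp(150 * 3, 1 / 30), 150, 3)
    p <- c(0.05, 0.45, 0.5)
    t <- rnbinom(150, mu = drop(C %*% p), size = 5)
    e_d <- abs(postprocess_proportions(solve_dwls(C, t))[1] - 0.05)
    e_n <- abs(postprocess_proportions(solve_nnls(C, t))[1] - 0.05)
    wins <- wins + (e_d <= e_n)
  }
  expect_gte(wins, 160)                # >= 80% of 200 seeded trials
  ## damping cap 1 makes every weight equal: identical to plain NNLS
  fx <- solver_fixture()
  t <- fx$t * (1 + rnorm(length(fx$t), 0, 0.05))
  expect_equal(as.numeric(solve_dwls(fx$C, t, damping_grid = 1)),
               solve_nnls(fx$C, t), tolerance = 1e-6)
})

test_that("post-processing clips, renormalizes and flags degenerates", {
  expect_equal(unname(postprocess_proportions(c(-0.1, 0.6, 0.5))),
               c(0, 6 / 11, 5 / 11))
  v <- c(0.2, 0.3, 0.5)
  expect_equal(unname(postprocess_proportions(v)), v)
  z <- postprocess_proportions(c(0, 0, 0))
  expect_true(all(is.na(z)))
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_error(postprocess_proportions(c(NaN, 1)), "NaN")
})

test_that("proportions are scale-equivariant for the main families", {
  set.seed(15)
  for (i in 1:5) {
    C <- matrix(rexp(80 * 4, 1 / 20), 80, 4)
    t <- drop(C %*% c(0.1, 0.2, 0.3, 0.4)) * (1 + rnorm(80, 0, 0.05))
    s <- runif(1, 0.1, 50)
    for (f in list(solve_ols, solve_nnls, solve_qp, solve_rlr)) {
      a <- postprocess_proportions(as.numeric(f(C, t)))
      b <- postprocess_proportions(as.numeric(f(C * s, t * s)))
      expect_equal(a, b, tolerance = 1e-6)
    }
  }
})

test_that("deconvolve recovers exact linear mixtures end to end", {
  pp <- pancreas_pipeline()
  C <- subset_to_markers(pp$C, pp$markers)
  set.seed(16)
  P <- sapply(1:40, function(i) {
    p <- rep(0, ncol(C)); idx <- sample(ncol(C), 3)
    p[idx] <- c(0.2, 0.3, 0.5); p
  })
  rownames(P) <- colnames(C)
  mix <- structure(list(
    T = unclass(C) %*% P, P_E = P,
    provenance = vector("list", 40),
    rules = composition_rules(n_mixtures = 40)), class = "MixtureSet")
  colnames(mix$T) <- colnames(mix$P_E) <- sprintf("mix%02d", 1:40)
  res <- deconvolve(mix, C, NULL, "nnls", "linear", "none", "none")
  expect_lt(proportion_rmse(mix$P_E, res$P_C), 1e-6)
  res2 <- deconvolve(mix, C, NULL, "nnls", "linear", "none", "none")
  expect_identical(res$P_C, res2$P_C)
})

test_that("incompatible combinations come back as recorded skips", {
  pp <- pancreas_pipeline()
  small <- pp$mix
  small$T <- small$T[, 1:3]; small$P_E <- small$P_E[, 1:3]
  small$provenance <- small$provenance[1:3]
  res <- deconvolve(small, pp$C, pp$markers, "nnls", "linear",
                    "column_zscore", "column_zscore")
  expect_true(res$skipped)
  expect_match(res$reason, "negative")
  res2 <- deconvolve(small, pp$C, pp$markers, "nnls", "log",
                     "median_ratios", "median_ratios")
  expect_true(res2$skipped)
  expect_error(deconvolve(small, pp$C, pp$markers, "no_such_method"),
               "unknown solver")
})

test_that("external solvers can be registered and driven through the grid", {
  register_solver("halfhalf", function(C, t, ...) rep(1, ncol(C)))
  expect_true("halfhalf" %in% names(solver_registry()))
  pp <- pancreas_pipeline()
  small <- pp$mix
  small$T <- small$T[, 1:2]; small$P_E <- small$P_E[, 1:2]
  small$provenance <- small$provenance[1:2]
  res <- deconvolve(small, pp$C, pp$markers, "halfhalf")
  expect_equal(unname(res$P_C[, 1]), rep(1 / ncol(pp$C), ncol(pp$C)))
})
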