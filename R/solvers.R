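#' Ordinary least squares deconvolution of one mixture
#'
#' Minimizes ||C p - t||^2 without constraints. Rank-deficient references
#' give the minimum-norm solution with a warning.
#'
#' @param C signature matrix (genes x cell types).
#' @param t mixture expression vector.
#' @return unconstrained coefficient vector.
#' @export
solve_ols <- function(C, t) .ls_solve(C, t, warn = TRUE)

#' Non-negative least squares deconvolution (Lawson-Hanson)
#'
#' @inheritParams solve_ols
#' @return coefficient vector with every entry >= 0.
#' @export
solve_nnls <- function(C, t) nnls_lh(C, t)

#' Robust (Huber) regression deconvolution
#'
#' Iteratively reweighted least squares with Huber weights
#' w_i = min(1, k s / |r_i|), where s is the MAD scale of the residuals and
#' k the Huber tuning constant; k -> Inf reproduces OLS.
#'
#' @inheritParams solve_ols
#' @param tuning Huber constant (1.345 gives 95% normal efficiency).
#' @param max_iter,tol convergence controls on the coefficient change.
#' @return coefficient vector; attribute `converged` reports convergence.
#' @export
solve_rlr <- function(C, t, tuning = 1.345, max_iter = 100L, tol = 1e-8) {
  p <- .ls_solve(C, t)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    r <- t - drop(C %*% p)
    s <- .mad(r)
    if (s <= .Machine$double.eps) { converged <- TRUE; break }
    w <- pmin(1, tuning * s / pmax(abs(r), .Machine$double.eps))
    p_new <- .ls_solve(C * sqrt(w), sqrt(w) * t)
    if (max(abs(p_new - p)) < tol * max(1, max(abs(p)))) {
      p <- p_new; converged <- TRUE; break
    }
    p <- p_new
  }
  if (!converged)
    attr(p, "converged") <- FALSE
  p
}

#' Quadratic-programming deconvolution on the proportion simplex
#'
#' Minimizes ||C p - t||^2 subject to p >= 0 and sum(p) = 1, both enforced
#' in-solver (active set), so the output needs no post-hoc renormalization.
#'
#' @inheritParams solve_ols
#' @return proportion vector on the simplex.
#' @export
solve_qp <- function(C, t) simplex_lsq(C, t)

#' Penalized regression deconvolution (ridge, lasso, elastic net)
#'
#' Objective (1 / 2n) ||C p - t||^2 + lambda (mixing ||p||_1 +
#' (1 - mixing) / 2 ||p||^2), fitted by closed form (ridge) or coordinate
#' descent; lambda is chosen by cross-validation over genes, minimizing
#' held-out reconstruction error.
#'
#' @inheritParams solve_ols
#' @param penalty `"ridge"`, `"lasso"` or `"elastic_net"`.
#' @param lambda_grid decreasing penalty grid; by default 30 log-spaced
#'   values from the data-driven lambda_max down to 1e-4 lambda_max.
#' @param mixing elastic-net mixing (lasso fraction) used when
#'   `penalty = "elastic_net"`.
#' @param cv_folds gene folds for lambda selection.
#' @param seed seed for the fold assignment.
#' @return coefficient vector at the selected lambda.
#' @export
solve_penalized <- function(C, t, penalty = c("ridge", "lasso", "elastic_net"),
                            lambda_grid = NULL, mixing = 0.5, cv_folds = 5L,
                            seed = 1L) {
  penalty <- match.arg(penalty)
  n <- nrow(C)
  alpha <- switch(penalty, ridge = 0, lasso = 1, elastic_net = mixing)
  if (is.null(lambda_grid)) {
    lmax <- max(abs(crossprod(C, t))) / (n * max(alpha, 1e-3))
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 30L))
  }
  if (!length(lambda_grid)) .stopf("empty lambda grid")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  fit_one <- function(Ctr, ttr, lambda) {
    if (alpha == 0) {
      ntr <- nrow(Ctr)
      return(drop(solve(crossprod(Ctr) / ntr + diag(lambda, ncol(Ctr)),
                        crossprod(Ctr, ttr) / ntr)))
    }
    .coord_descent(Ctr, ttr, lambda, alpha)
  }
  if (length(lambda_grid) > 1L) {
    folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
    cv_err <- numeric(length(lambda_grid))
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      for (li in seq_along(lambda_grid)) {
        p <- fit_one(C[tr, , drop = FALSE], t[tr], lambda_grid[li])
        r <- t[!tr] - drop(C[!tr, , drop = FALSE] %*% p)
        cv_err[li] <- cv_err[li] + sum(r^2)
      }
    }
    lambda <- lambda_grid[which.min(cv_err)]
  } else lambda <- lambda_grid
  out <- fit_one(C, t, lambda)
  attr(out, "lambda") <- lambda
  out
}

## elastic-net coordinate descent, glmnet-style scaling, no intercept,
## no standardization
.coord_descent <- function(A, b, lambda, alpha, max_iter = 1000L, tol = 1e-9) {
  n <- nrow(A); k <- ncol(A)
  x <- numeric(k)
  xx <- colSums(A^2) / n
  r <- b
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(k)) {
      rho <- sum(A[, j] * r) / n + xx[j] * x[j]
      new <- soft(rho, lambda * alpha) / (xx[j] + lambda * (1 - alpha))
      if (new != x[j]) {
        r <- r - A[, j] * (new - x[j])
        delta <- max(delta, abs(new - x[j]))
        x[j] <- new
      }
    }
    if (delta < tol) break
  }
  x
}

#' Linear nu-support-vector regression deconvolution (CIBERSORT-style)
#'
#' The signature columns (features) and the mixture are z-scored, a linear
#' nu-SVR of t on C is fitted for each nu in `nu_grid`, and the
#' coefficients of the model with the smallest root-mean-square error
#' between fitted and observed mixture are returned. Negative coefficients
#' are left to [postprocess_proportions()].
#'
#' The nu-SVR is solved in its primal form min 1/2 ||w||^2 + cost (nu eps +
#' mean(max(0, |t - C w - b| - eps))) over (w, b, eps) — a low-dimensional
#' convex problem — by smoothed-hinge BFGS with a continuation schedule on
#' the smoothing temperature.
#'
#' @inheritParams solve_ols
#' @param nu_grid candidate nu values.
#' @param cost SVR cost parameter.
#' @return coefficient vector (on the original column scale); attributes
#'   `nu` (selected value) and `fit_rmse` (per-nu fit errors).
#' @export
solve_svr <- function(C, t, nu_grid = c(0.25, 0.5, 0.75), cost = 1) {
  k <- ncol(C)
  mu <- colMeans(C); sdv <- apply(C, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(C, 2L, mu, "-"), 2L, sdv, "/")
  ty_mu <- mean(t); ty_sd <- stats::sd(t)
  if (ty_sd == 0) ty_sd <- 1
  y <- (t - ty_mu) / ty_sd
  fits <- lapply(nu_grid, function(nu) .nu_svr_primal(X, y, nu, cost))
  rmse <- vapply(seq_along(fits), function(i) {
    w <- fits[[i]]$w
    ## CIBERSORT-style model selection: RMSE between the reconstructed and
    ## observed (z-scored) mixture
    sqrt(mean((drop(X %*% w) + fits[[i]]$b - y)^2))
  }, numeric(1))
  if (all(!is.finite(rmse))) {
    out <- rep(NA_real_, k)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  best <- which.min(rmse)
  w <- fits[[best]]$w
  ## undo the feature scaling so coefficients live on C's original columns
  out <- w / sdv * ty_sd
  attr(out, "nu") <- nu_grid[best]
  attr(out, "fit_rmse") <- stats::setNames(rmse, nu_grid)
  out
}

## smoothed primal nu-SVR: theta = (w, b, eps); hinge smoothed by
## tau * log1p(exp(u / tau)) with decreasing tau. The cost follows the
## libsvm convention (per-sample): 1/2 ||w||^2 + cost (nu n eps + sum xi)
.nu_svr_primal <- function(X, y, nu, cost) {
  n <- nrow(X); k <- ncol(X)
  cost <- cost * n
  obj_grad <- function(theta, tau) {
    w <- theta[seq_len(k)]; b <- theta[k + 1L]; eps <- theta[k + 2L]
    r <- y - drop(X %*% w) - b
    u <- abs(r) - eps
    ue <- u / tau
    sp <- ifelse(ue > 30, u, tau * log1p(exp(pmin(ue, 30))))
    sig <- 1 / (1 + exp(-pmin(pmax(ue, -30), 30)))
    f <- 0.5 * sum(w^2) + cost * (nu * eps + mean(sp))
    ## df/dr_i = -(cost/n) sig_i sign(r_i); r = y - Xw - b
    s <- cost / n * sig * sign(r)
    g_w <- w - drop(crossprod(X, s))
    g_b <- -sum(s)
    g_eps <- cost * nu - cost / n * sum(sig)
    list(value = f, gradient = c(g_w, g_b, g_eps))
  }
  theta <- c(.ls_solve(X, y), 0, stats::sd(y) * 0.1)
  for (tau in c(0.05, 0.005, 5e-4)) {
    fit <- try(stats::optim(theta,
                            fn = function(th) obj_grad(th, tau)$value,
                            gr = function(th) obj_grad(th, tau)$gradient,
                            method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(list(w = rep(NA_real_, k), b = NA_real_))
    theta <- fit$par
  }
  list(w = theta[seq_len(k)], b = theta[k + 1L], eps = theta[k + 2L])
}

#' Dampened weighted least squares deconvolution
#'
#' Starts from NNLS, then iterates non-negative weighted least squares with
#' per-gene weights 1 / (C p)^2 whose scaled values are capped at a damping
#' constant. The constant is chosen once, from the damping grid, by
#' cross-validation on gene subsets (minimizing held-out weighted
#' reconstruction error under the initial weights); iteration stops when
#' the coefficient change falls below `tol`. The marker selection used with
#' this solver is the package's own marker module (or all genes), not the
#' internal selection of the original single-cell method.
#'
#' @inheritParams solve_ols
#' @param damping_grid candidate weight ceilings (powers of two).
#' @param cv_folds gene folds for choosing the damping constant.
#' @param max_iter,tol convergence controls.
#' @param seed seed for the fold assignment.
#' @return coefficient vector >= 0; attribute `damping` records the chosen
#'   constant.
#' @export
solve_dwls <- function(C, t, damping_grid = 2^(0:10), cv_folds = 4L,
                       max_iter = 100L, tol = 1e-7, seed = 1L) {
  n <- nrow(C)
  p <- nnls_lh(C, t)
  weights_for <- function(p, cap) {
    pred <- drop(C %*% p)
    w <- 1 / pmax(pred, .Machine$double.eps)^2
    ws <- w / min(w[is.finite(w)])
    pmin(ws, cap)
  }
  ## pick the damping constant by CV on gene subsets, using the
  ## NNLS-initialized weights
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv_err <- vapply(damping_grid, function(cap) {
    w <- weights_for(p, cap)
    err <- 0
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      pf <- nnls_lh(C[tr, , drop = FALSE] * sqrt(w[tr]), t[tr] * sqrt(w[tr]))
      r <- t[!tr] - drop(C[!tr, , drop = FALSE] %*% pf)
      err <- err + sum(w[!tr] * r^2)
    }
    err
  }, numeric(1))
  cap <- damping_grid[which.min(cv_err)]
  for (i in seq_len(max_iter)) {
    w <- weights_for(p, cap)
    p_new <- nnls_lh(C * sqrt(w), t * sqrt(w))
    if (max(abs(p_new - p)) < tol * max(1, max(abs(p)))) { p <- p_new; break }
    p <- p_new
  }
  attr(p, "damping") <- cap
  p
}

#' Turn raw solver coefficients into proportions
#'
#' Negative coefficients are clipped to zero and the vector renormalized to
#' sum one. An all-zero (or all-missing) raw vector cannot be interpreted
#' as a composition: the result is all `NA` with attribute
#' `degenerate = TRUE`.
#'
#' @param raw coefficient vector.
#' @return proportion vector summing to 1, or all-`NA` if degenerate.
#' @export
postprocess_proportions <- function(raw) {
  if (any(is.nan(raw))) .stopf("NaN coefficients cannot be post-processed")
  if (all(is.na(raw))) {
    out <- raw
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- pmax(as.numeric(raw), 0)
  s <- sum(p)
  if (s == 0) {
    out <- rep(NA_real_, length(raw))
    names(out) <- names(raw)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- p / s
  names(out) <- names(raw)
  out
}

#' The solver registry
#'
#' Maps solver ids to functions of `(C, t, ...)` returning raw
#' coefficients. The built-ins are `ols`, `nnls`, `rlr`, `qp`, `ridge`,
#' `lasso`, `elastic_net`, `svr` and `dwls`; external methods (FARDEEP,
#' MuSiC, EPIC, ...) can be wrapped with [register_solver()] so the harness
#' can drive them through the same grid.
#'
#' @return named list of solver functions.
#' @export
solver_registry <- function() as.list(.solver_env)

.solver_env <- new.env(parent = emptyenv())

#' Register an external solver
#' @param id character id.
#' @param fn function `(C, t, ...)` returning a coefficient vector.
#' @export
register_solver <- function(id, fn) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  assign(id, fn, envir = .solver_env)
  invisible(id)
}

.init_solvers <- function() {
  register_solver("ols", function(C, t, ...) solve_ols(C, t))
  register_solver("nnls", function(C, t, ...) solve_nnls(C, t))
  register_solver("rlr", function(C, t, ...) solve_rlr(C, t, ...))
  register_solver("qp", function(C, t, ...) solve_qp(C, t))
  register_solver("ridge", function(C, t, ...) solve_penalized(C, t, "ridge", ...))
  register_solver("lasso", function(C, t, ...) solve_penalized(C, t, "lasso", ...))
  register_solver("elastic_net", function(C, t, ...) solve_penalized(C, t, "elastic_net", ...))
  register_solver("svr", function(C, t, ...) solve_svr(C, t, ...))
  register_solver("dwls", function(C, t, ...) solve_dwls(C, t, ...))
}

#' Default method panel
#'
#' The five top-performing bulk method families of the benchmark: NNLS,
#' CIBERSORT-style SVR, robust regression, quadratic programming and
#' dampened weighted least squares.
#' @export
DEFAULT_METHODS <- c("nnls", "svr", "rlr", "qp", "dwls")

#' Run one (transform, normalization, marker, method) combination
#'
#' Applies the transformation to both the mixtures and the reference,
#' normalizes them (scalingT for the mixtures, scalingC for the reference;
#' either may be a function for plugin normalizers), restricts both to the
#' marker union (bulk path) and solves every mixture, post-processing the
#' coefficients into proportions. Incompatible combinations (per
#' [check_compatibility()]) come back as a recorded skip, not a failure.
#'
#' @param mix a `MixtureSet`.
#' @param C a `ReferenceMatrix`.
#' @param markers a `MarkerSet`, or `NULL` to use all genes.
#' @param method solver id in [solver_registry()].
#' @param transform transformation kind.
#' @param scalingT,scalingC normalization kinds (or functions) for mixtures
#'   and reference.
#' @param ... passed to the solver.
#' @return a `DeconvolutionResult`: list with `P_C` (cell type x mixture),
#'   `raw`, `degenerate` (logical per mixture), `skipped`, `reason` and the
#'   combination metadata.
#' @export
deconvolve <- function(mix, C, markers = NULL, method = "nnls",
                       transform = "linear", scalingT = "none",
                       scalingC = "none", ...) {
  stopifnot(inherits(mix, "MixtureSet"))
  meta <- list(method = method, transform = transform,
               scalingT = if (is.function(scalingT)) "custom" else scalingT,
               scalingC = if (is.function(scalingC)) "custom" else scalingC,
               marker_strategy = if (is.null(markers)) "none" else markers$strategy,
               pool_size = mix$rules$pool_size)
  skip <- function(reason)
    structure(c(list(P_C = NULL, raw = NULL, degenerate = NULL,
                     skipped = TRUE, reason = reason), meta),
              class = "DeconvolutionResult")
  for (sc in list(scalingT, scalingC)) {
    if (is.character(sc)) {
      chk <- check_compatibility(transform, sc, method)
      if (!chk$ok) return(skip(chk$reason))
    }
  }
  solver <- solver_registry()[[method]]
  if (is.null(solver)) .stopf("unknown solver id: %s", method)

  norm_apply <- function(M, sc) if (is.function(sc)) sc(M) else
    normalize_expression(M, sc)
  T_mat <- norm_apply(transform_expression(mix$T, transform), scalingT)
  C_mat <- norm_apply(transform_expression(unclass(C), transform), scalingC)
  if (!is.null(markers)) {
    genes <- unique(unlist(markers$markers, use.names = FALSE))
    genes <- intersect(rownames(C_mat), genes)
    if (!length(genes)) return(skip("empty marker set after filtering"))
    C_mat <- C_mat[genes, , drop = FALSE]
    T_mat <- T_mat[genes, , drop = FALSE]
  }
  n_mix <- ncol(T_mat)
  P_C <- matrix(NA_real_, ncol(C_mat), n_mix,
                dimnames = list(colnames(C_mat), colnames(T_mat)))
  raw <- P_C
  degenerate <- logical(n_mix)
  for (m in seq_len(n_mix)) {
    coefs <- solver(C_mat, T_mat[, m], ...)
    raw[, m] <- as.numeric(coefs)
    p <- postprocess_proportions(as.numeric(coefs))
    degenerate[m] <- isTRUE(attr(p, "degenerate"))
    P_C[, m] <- p
  }
  structure(c(list(P_C = P_C, raw = raw, degenerate = degenerate,
                   skipped = FALSE, reason = ""), meta),
            class = "DeconvolutionResult")
}

#' @export
print.DeconvolutionResult <- function(x, ...) {
  if (x$skipped)
    cat(sprintf("DeconvolutionResult [skipped]: %s / %s / T:%s C:%s — %s\n",
                x$method, x$transform, x$scalingT, x$scalingC, x$reason))
  else
    cat(sprintf("DeconvolutionResult: %s / %s / T:%s C:%s, %d mixtures (%d degenerate)\n",
                x$method, x$transform, x$scalingT, x$scalingC,
                ncol(x$P_C), sum(x$degenerate)))
  invisible(x)
}
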