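## Dense least-squares machinery used by the solver layer. All of it is
## self-contained: the regression families the benchmark compares are
## implemented from their definitions, not wrapped from other packages.

## Lawson-Hanson active-set non-negative least squares:
## min ||A x - b||^2 s.t. x >= 0
nnls_lh <- function(A, b, tol = NULL, max_iter = NULL) {
  n <- ncol(A)
  tol <- tol %||% (10 * .Machine$double.eps * sum(abs(A)) * max(dim(A)))
  max_iter <- max_iter %||% (30L * n)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- .ls_solve(Ap, b)
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

## least-squares solve, falling back to the minimum-norm solution for
## rank-deficient systems
.ls_solve <- function(A, b, warn = FALSE) {
  qra <- qr(A)
  if (qra$rank == ncol(A)) return(drop(qr.coef(qra, b)))
  if (warn) warning("rank-deficient system: returning minimum-norm solution",
                    call. = FALSE)
  sv <- svd(A)
  pos <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1L]
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos]))
}

## active-set quadratic program for the proportion simplex:
## min ||A x - b||^2 s.t. sum(x) = 1, x >= 0
simplex_lsq <- function(A, b, tol = 1e-10, max_iter = NULL) {
  k <- ncol(A)
  max_iter <- max_iter %||% (50L * k)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  scale <- mean(diag(AtA)) + 1
  solve_eq <- function(free) {
    nf <- sum(free)
    K <- rbind(cbind(AtA[free, free, drop = FALSE], scale),
               c(rep(scale, nf), 0))
    rhs <- c(Atb[free], scale)
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      ## singular KKT system (duplicated columns): minimum-norm solution
      sv <- svd(K)
      pos <- sv$d > max(sv$d) * 1e-12
      drop(sv$v[, pos, drop = FALSE] %*%
             (crossprod(sv$u[, pos, drop = FALSE], rhs) / sv$d[pos]))
    })
    sol[seq_len(nf)]
  }
  x <- rep(1 / k, k)
  free <- rep(TRUE, k)
  for (iter in seq_len(max_iter)) {
    s <- numeric(k)
    s[free] <- solve_eq(free)
    if (any(s[free] < -tol)) {
      ## step from x toward s, stopping at the first variable hitting zero
      d <- s - x
      viol <- free & s < -tol & d < 0
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * d
      x[free & x <= tol] <- 0
      free <- free & x > tol
      if (!any(free)) { free[which.max(Atb)] <- TRUE }
      next
    }
    x <- s
    x[!free] <- 0
    ## dual check on the active bounds: mu_i = g_i - lambda must be >= 0
    g <- drop(AtA %*% x) - Atb
    lambda <- mean(g[free])
    mu <- g - lambda
    worst <- which(!free & mu < -sqrt(tol))
    if (!length(worst)) return(x)
    free[worst[which.min(mu[worst])]] <- TRUE
  }
  x / sum(x)
}
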