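#' Available normalization kinds
#'
#' The closed-form rows of the benchmark's normalization table plus
#' `"none"`. Single-cell-specific methods (scran, scater, Linnorm,
#' SCTransform) are their own published methods and are only reachable via
#' the plugin hook of [deconvolve()].
#' @export
NORMALIZATION_KINDS <- c("none", "column", "column_minmax", "column_zscore",
                         "row", "global_minmax", "global_zscore", "quantile",
                         "upper_quartile", "tpm", "tmm", "lognormalize_linear",
                         "median_ratios")

#' Scaling and normalization strategies
#'
#' The closed-form scaling/normalization strategies of the benchmark grid.
#' Contracts: `column`, `row`, `column_minmax`, `global_minmax` are bounded
#' in \[0, 1\]; only the z-score variants may produce negative values.
#'
#' * `column`: each column scaled to sum 1 (library-size normalization).
#' * `column_minmax` / `global_minmax`: (x - min) / (max - min) per column
#'   or matrix-wide.
#' * `column_zscore` / `global_zscore`: (x - mean) / sd per column or
#'   matrix-wide.
#' * `row`: each row scaled to sum 1 (all-zero rows stay zero).
#' * `quantile`: classic rank substitution against the mean of the sorted
#'   columns; tied ranks receive the mean of the reference values they span.
#' * `upper_quartile`: each column divided by the 75th percentile of its
#'   nonzero values; fails if any column's quartile is undefined or zero.
#' * `tpm`: rows divided by gene length (kb), columns scaled to 1e6; unit
#'   lengths (the UMI default) reduce it to counts per million.
#' * `tmm`: trimmed-mean-of-M-values factors ([tmm_factors()]) followed by
#'   counts per million on the factor-adjusted library sizes.
#' * `lognormalize_linear`: column total scaling to `scale_factor`, log1p,
#'   then expm1 back to linear scale.
#' * `median_ratios`: each column divided by its median-of-ratios size
#'   factor ([median_ratio_size_factors()]); defined on linear-scale counts.
#'
#' @param M numeric matrix (genes x samples), finite; non-negative except
#'   where noted.
#' @param kind one of `r paste(NORMALIZATION_KINDS, collapse = ", ")`.
#' @param gene_lengths length vector in bases for `tpm`; default unit
#'   lengths.
#' @param scale_factor column total used by `lognormalize_linear`.
#' @param constant_zscore what a z-score should do with a constant column
#'   (`"error"` or `"zero"`).
#' @return normalized matrix, same shape and dimnames.
#' @export
normalize_expression <- function(M, kind = NORMALIZATION_KINDS,
                                 gene_lengths = NULL, scale_factor = 1e4,
                                 constant_zscore = c("error", "zero")) {
  kind <- match.arg(kind)
  constant_zscore <- match.arg(constant_zscore)
  if (!is.matrix(M)) M <- as.matrix(M)
  if (any(!is.finite(M))) .stopf("normalize input must be finite")
  zs <- function(x, mu, s) {
    if (s == 0) {
      if (constant_zscore == "error") .stopf("constant values: z-score undefined")
      return(x * 0)
    }
    (x - mu) / s
  }
  switch(kind,
    none = M,
    column = {
      cs <- colSums(M)
      if (any(cs == 0)) .stopf("column normalization: zero column total")
      sweep(M, 2L, cs, "/")
    },
    column_minmax = {
      rng <- apply(M, 2L, range)
      if (any(rng[2L, ] == rng[1L, ])) .stopf("constant column: min-max undefined")
      sweep(sweep(M, 2L, rng[1L, ], "-"), 2L, rng[2L, ] - rng[1L, ], "/")
    },
    column_zscore = {
      out <- M
      for (j in seq_len(ncol(M)))
        out[, j] <- zs(M[, j], mean(M[, j]), stats::sd(M[, j]))
      out
    },
    row = {
      rs <- rowSums(M)
      sweep(M, 1L, ifelse(rs == 0, 1, rs), "/")
    },
    global_minmax = {
      r <- range(M)
      if (r[1L] == r[2L]) .stopf("constant matrix: min-max undefined")
      (M - r[1L]) / (r[2L] - r[1L])
    },
    global_zscore = {
      out <- zs(as.vector(M), mean(M), stats::sd(as.vector(M)))
      matrix(out, nrow(M), ncol(M), dimnames = dimnames(M))
    },
    quantile = quantile_normalize(M),
    upper_quartile = {
      uq <- apply(M, 2L, function(x) {
        nz <- x[x > 0]
        if (!length(nz)) NA_real_ else stats::quantile(nz, 0.75, names = FALSE)
      })
      if (any(!is.finite(uq)) || any(uq == 0))
        .stopf("upper-quartile normalization failed: normalization factors are zero or NA")
      sweep(M, 2L, uq, "/")
    },
    tpm = {
      len <- gene_lengths %||% rep(1e3, nrow(M))
      if (length(len) != nrow(M)) .stopf("gene_lengths must have one entry per gene")
      rate <- sweep(M, 1L, len / 1e3, "/")
      cs <- colSums(rate)
      if (any(cs == 0)) .stopf("tpm: zero column total")
      sweep(rate, 2L, cs, "/") * 1e6
    },
    tmm = {
      if (any(M < 0)) .stopf("tmm requires non-negative values")
      f <- tmm_factors(M)
      eff <- colSums(M) * f
      sweep(M, 2L, eff, "/") * 1e6
    },
    lognormalize_linear = {
      cs <- colSums(M)
      if (any(cs == 0)) .stopf("lognormalize: zero column total")
      expm1(log1p(sweep(M, 2L, cs, "/") * scale_factor))
    },
    median_ratios = {
      if (any(M < 0)) .stopf("median-of-ratios requires non-negative linear-scale values")
      sf <- median_ratio_size_factors(M)
      sweep(M, 2L, sf, "/")
    })
}

#' Quantile normalization
#'
#' Every column is forced onto the common reference distribution given by
#' the row-wise means of the sorted columns. Tied ranks receive the mean of
#' the reference values they span.
#'
#' @param M numeric matrix.
#' @return normalized matrix.
#' @export
quantile_normalize <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  ref <- rowMeans(apply(M, 2L, sort))
  out <- M
  for (j in seq_len(ncol(M))) {
    r <- rank(M[, j], ties.method = "average")
    out[, j] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}

#' Trimmed mean of M-values scaling factors
#'
#' Canonical defaults: reference column = the one whose upper quartile of
#' library-size-scaled counts is closest to the mean upper quartile;
#' two-sided trimming of M-values at 30% and A-values at 5%; weights from
#' the inverse asymptotic (binomial) variance. Genes with a zero in the
#' reference or the sample are excluded. Factors are scaled to have
#' geometric mean 1.
#'
#' @param M non-negative count matrix (genes x samples).
#' @param logratio_trim,sum_trim two-sided trim fractions for M and A.
#' @return numeric vector of scaling factors, one per column.
#' @export
tmm_factors <- function(M, logratio_trim = 0.3, sum_trim = 0.05) {
  if (!is.matrix(M)) M <- as.matrix(M)
  lib <- colSums(M)
  if (any(lib == 0)) .stopf("tmm: zero library size")
  M <- M[rowSums(M > 0) > 0L, , drop = FALSE]  # all-zero genes carry no signal
  uq <- apply(sweep(M, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75, names = FALSE)
  ref_j <- if (stats::median(uq) < 1e-20) which.max(colSums(sqrt(M)))
           else which.min(abs(uq - mean(uq)))
  r <- M[, ref_j]; Nr <- lib[ref_j]
  f <- vapply(seq_len(ncol(M)), function(j) {
    if (j == ref_j) return(1)
    x <- M[, j]; N <- lib[j]
    keep <- x > 0 & r > 0
    if (!any(keep)) return(NA_real_)
    xx <- x[keep]; rr <- r[keep]
    m_val <- log2((xx / N) / (rr / Nr))
    a_val <- 0.5 * log2((xx / N) * (rr / Nr))
    w <- (N - xx) / (N * xx) + (Nr - rr) / (Nr * rr)
    n <- length(m_val)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
    keep2 <- rank(m_val) >= lo_m & rank(m_val) <= hi_m &
             rank(a_val) >= lo_a & rank(a_val) <= hi_a
    if (!any(keep2)) return(1)
    2^(sum(m_val[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  if (any(!is.finite(f))) .stopf("tmm: normalization factors are infinite or NA")
  f / exp(mean(log(f)))
}

#' Median-of-ratios size factors
#'
#' Each column's factor is the median over genes of the ratio of its counts
#' to the per-gene geometric mean, restricted to genes whose geometric mean
#' is positive (i.e. genes expressed in every sample).
#'
#' @param M non-negative matrix (genes x samples).
#' @return numeric vector of size factors, one per column.
#' @export
median_ratio_size_factors <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  logg <- rowMeans(log(M))          # -Inf for genes with any zero
  ok <- is.finite(logg)
  if (!any(ok))
    .stopf("median-of-ratios: no gene is expressed in every sample")
  vapply(seq_len(ncol(M)), function(j)
    exp(stats::median(log(M[ok, j]) - logg[ok])), numeric(1))
}

#' Check whether a transformation/normalization/solver combination is
#' feasible
#'
#' Mirrors the benchmark's excluded grid cells: median-of-ratios is only
#' defined on linear-scale counts; upper-quartile factors degenerate on
#' sparse single-cell input; solvers with a non-negativity model cannot take
#' z-scored (negative) matrices. Skips are reported with a reason so they
#' can be logged, never silently dropped.
#'
#' @param transform transformation kind (see [transform_expression()]).
#' @param normalization normalization kind (see [normalize_expression()]).
#' @param method solver id (see [solver_registry()]); `"any"` checks only
#'   data-level rules.
#' @param sparse_input set `TRUE` when the matrix to be normalized is sparse
#'   single-cell data (mostly zeros).
#' @return `list(ok = logical, reason = character)`.
#' @export
check_compatibility <- function(transform, normalization, method = "any",
                                sparse_input = FALSE) {
  skip <- function(reason) list(ok = FALSE, reason = reason)
  if (normalization == "median_ratios" && transform != "linear")
    return(skip("median-of-ratios requires linear integer counts"))
  if (normalization == "upper_quartile" && isTRUE(sparse_input))
    return(skip("upper-quartile factors degenerate on sparse single-cell input"))
  nonneg_methods <- c("nnls", "qp", "dwls")
  if (normalization %in% c("column_zscore", "global_zscore") &&
      method %in% nonneg_methods)
    return(skip(sprintf("z-scored input contains negative values; %s assumes non-negative expression", method)))
  list(ok = TRUE, reason = "")
}
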