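#' Data transformations compared by the benchmark
#'
#' Four elementwise transformations of non-negative expression matrices:
#' `linear` (identity), `log` (natural `log1p`), `sqrt`, and `vst` (a
#' closed-form negative-binomial variance stabilizer, see
#' [fit_vst_parameters()]). All preserve shape and ordering and are
#' monotone non-decreasing in every entry.
#'
#' The VST first normalizes columns by median-of-ratios size factors, then
#' applies the closed-form stabilizer for the NB variance function
#' v(mu) = mu (1 + a1) + a0 mu^2 with a parametric dispersion trend
#' alpha(mu) = a1 / mu + a0 fitted to the data by method of moments and
#' least squares. This is a functional stand-in for dedicated VST
#' implementations: it flattens the variance-mean trend but is not
#' numerically identical to any external package.
#'
#' @param M numeric matrix, finite and non-negative.
#' @param kind one of `"linear"`, `"log"`, `"sqrt"`, `"vst"`.
#' @param vst_params optional list from [fit_vst_parameters()]; fitted from
#'   `M` when missing. Supplying the parameters fitted on one matrix (e.g.
#'   the single-cell training data) keeps a whole grid on one scale.
#' @return transformed matrix, same dimnames.
#' @export
transform_expression <- function(M, kind = c("linear", "log", "sqrt", "vst"),
                                 vst_params = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(M)) M <- as.matrix(M)
  if (any(!is.finite(M))) .stopf("transform input must be finite")
  if (any(M < 0)) .stopf("transform input must be non-negative")
  switch(kind,
    linear = M,
    log = log1p(M),
    sqrt = sqrt(M),
    vst = {
      p <- vst_params %||% fit_vst_parameters(M)
      sf <- median_ratio_size_factors(M)
      if (any(!is.finite(sf)) || any(sf <= 0)) sf <- rep(1, ncol(M))
      Mn <- sweep(M, 2L, sf, "/")
      .vst_closed_form(Mn, p$extra_pois, p$asympt_disp)
    })
}

## closed-form integral of 1/sqrt(v(mu)) for v(mu) = mu(1+a1) + a0 mu^2,
## scaled to log2-like units; monotone, finite at 0
.vst_closed_form <- function(q, a1, a0) {
  log((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0)) / log(2)
}

#' Fit the parametric dispersion trend used by the VST
#'
#' Per-gene dispersions are estimated by method of moments on
#' size-factor-normalized counts (alpha = (var - mu) / mu^2) and the trend
#' alpha(mu) = a1 / mu + a0 is fitted by least squares over genes with
#' positive estimates.
#'
#' @param M non-negative count matrix (genes x samples).
#' @return list with `extra_pois` (a1, >= 0) and `asympt_disp` (a0, > 0).
#' @export
fit_vst_parameters <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  sf <- median_ratio_size_factors(M)
  if (any(!is.finite(sf)) || any(sf <= 0)) sf <- rep(1, ncol(M))
  Mn <- sweep(M, 2L, sf, "/")
  mu <- rowMeans(Mn)
  v <- .row_vars(Mn)
  ok <- mu > 0 & v > mu            # genes with over-dispersion signal
  if (sum(ok) < 2L) return(list(extra_pois = 0, asympt_disp = 0.1))
  alpha <- (v[ok] - mu[ok]) / mu[ok]^2
  X <- cbind(1 / mu[ok], 1)
  fit <- stats::lm.fit(X, alpha)
  a1 <- max(0, unname(fit$coefficients[1L]))
  a0 <- max(1e-8, unname(fit$coefficients[2L]))
  list(extra_pois = a1, asympt_disp = a0)
}
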