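#' @keywords internal
"_PACKAGE"

## internal assertion helper: stop() with the caller's message, no call echo
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && abs(x - round(x)) < 1e-8

#' Derive a reproducible per-stage seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage (data generation,
#' splitting, marker selection, mixture sampling, ...) gets its own seed so
#' stages can be rerun independently yet reproducibly. The derivation is a
#' small deterministic hash of the stage name folded into the master seed,
#' kept below 2^31 so it is always a valid R integer.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483629
  as.integer((abs(master) %% 2147483629 * 7919 + h) %% 2147483628 + 1)
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## median absolute deviation with configurable consistency constant
.mad <- function(x, constant = 1.4826) constant * stats::median(abs(x - stats::median(x)))
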