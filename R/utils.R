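#' @importFrom stats rnorm runif lm lm.fit coef residuals median var cov cor
#' @importFrom utils write.csv read.csv
NULL

## population variance (divisor N), the error metric used throughout
popVar <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}

popCov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

clipCounts <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## evaluate a polynomial with ascending coefficients (c0 + c1 t + ...), Horner
polyvalAsc <- function(coeffs, t) {
  r <- rep(0, length(t))
  for (ck in rev(coeffs)) r <- r * t + ck
  r
}

## run expr under a temporary RNG state; the global stream is untouched
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic child seed from a base seed and one or more integer tags;
## stays below 2^31 (R integers are 32-bit); exact in double arithmetic
deriveSeed <- function(base, ...) {
  m <- 2147483629
  s <- as.numeric(base) %% m
  for (k in c(...)) {
    s <- (s * 48271 + (as.numeric(k) %% m) * 16807 + 12345) %% m
  }
  as.integer(s)
}

isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
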