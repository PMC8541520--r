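## Independent oracles and fixture builders. These deliberately avoid the
## package's own code paths: least squares via explicit normal equations,
## the scaling constant via brute-force grid search, homographies via a
## null-space DLT solve.

## OLS coefficients from the normal equations on the monomial basis
normalEqCoeffs <- function(t, y, order) {
  X <- outer(t, 0:order, `^`)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

## brute-force search for the constant minimizing the population variance
## of y - d * yhat
gridSearchD <- function(y, yhat, dGrid = seq(0, 1.5, by = 1e-4)) {
  M <- outer(dGrid, yhat)
  R <- matrix(y, nrow(M), ncol(M), byrow = TRUE) - M
  e <- rowMeans((R - rowMeans(R))^2)
  i <- which.min(e)
  list(d = dGrid[i], error = e[i])
}

## population variance, written independently of the package internals
oraclePopVar <- function(x) sum((x - sum(x) / length(x))^2) / length(x)

## homography via the 9-parameter DLT null space (SVD), scaled to H[3,3] = 1
dltHomography <- function(src, dst) {
  A <- matrix(0, 8, 9)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y, -v)
  }
  h <- svd(A, nv = 9)$v[, 9]
  matrix(h / h[9], 3, 3, byrow = TRUE)
}

## Horner-free polynomial evaluation (plain powers sum)
powerSumPolyval <- function(coeffs, t) {
  out <- numeric(length(t))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * t^(k - 1)
  out
}

## evaluate expr under a fixed RNG seed
withSeedFixture <- function(seed, expr) {
  set.seed(seed)
  expr
}

## standard simulated brightness series for one camera
makeSeries <- function(gamma = 1, noiseSigma = 0, gain = 220, offset = 0,
                       seed = 1, dim = c(32L, 192L),
                       levels = c(100, 80, 60, 40, 20),
                       coeffs = c(0.6, 0.5, -0.35, 0.25), id = "cam") {
  cam <- CameraModel(id, gain = gain, gamma = gamma, offset = offset,
                     noiseSigma = noiseSigma)
  imgs <- simulatePWMSeries(cam, IlluminationField(coeffs), levels = levels,
                            dim = dim, seed = seed)
  profileSeries(imgs, id)
}
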