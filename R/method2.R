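#' Fit the duty-100 reference profile
#'
#' Order-3 polynomial fit of the brightest (reference) profile; every
#' lower-brightness profile is then explained as a scalar multiple of this
#' fit. Delegates to \code{\link{fitPolynomial}}.
#'
#' @param profile the duty-100 \linkS4class{IntensityProfile}.
#' @param order fit order (default 3; the cubic captures typical LED +
#'   diffuser spatial profiles).
#' @return a \linkS4class{PolynomialFit}.
#' @export
fitReference <- function(profile, order = 3) fitPolynomial(profile, order)

#' Optimal scaling constant of a profile against the reference fit
#'
#' Finds the constant d minimizing the population variance of
#' \code{y_w - d * yhat_100(t)}. Because scaling a polynomial's coefficients
#' scales its values, this is exactly the best scalar multiple of the
#' reference fit. The quadratic objective gives the closed form
#' \code{d = cov(y_w, yhat_100) / var(yhat_100)}, and the error at the
#' optimum equals \code{var(y_w) * (1 - rho^2)} with rho the correlation of
#' y_w and yhat_100.
#'
#' @param profile an \linkS4class{IntensityProfile} on the reference fit's
#'   t grid.
#' @param referenceFit the duty-100 \linkS4class{PolynomialFit}.
#' @return list with \code{d} and \code{error}.
#' @export
optimalScalingConstant <- function(profile, referenceFit) {
  stopifnot(is(profile, "IntensityProfile"), is(referenceFit, "PolynomialFit"))
  if (length(profile@t) != length(referenceFit@t) ||
      max(abs(profile@t - referenceFit@t)) > 1e-12)
    stop("profile and reference fit are not on the same t grid")
  yhat <- referenceFit@fitted
  vref <- popVar(yhat)
  if (vref <= .Machine$double.eps * max(1, mean(yhat)^2))
    stop("reference profile has no spatial variation")
  d <- popCov(profile@y, yhat) / vref
  list(d = d, error = popVar(profile@y - d * yhat))
}

#' Per-level optimal scaling constants and the linearity score
#'
#' The second-stage analysis: fit the duty-100 reference profile (order 3),
#' then for every lower duty level find the constant d_w that best scales the
#' reference fit onto that level's profile and the residual-variance error at
#' the optimum. For a radiometrically linear camera d_w equals the
#' proportional baseline w/100 (d = 1, 0.8, 0.6, 0.4, 0.2 at duties 100..20);
#' the root-mean-square deviation of d from that baseline over non-reference
#' levels is the scalar linearity score used to rank cameras (smaller =
#' more linear). Constants outside [0, 1.5] are flagged as suspicious but
#' never clipped.
#'
#' @param series a \linkS4class{PWMSeries}.
#' @param order reference fit order (default 3).
#' @return a \linkS4class{ScalingResult}.
#' @examples
#' cam <- CameraModel("linear", gain = 220, gamma = 1)
#' imgs <- simulatePWMSeries(cam, IlluminationField(), seed = 1)
#' res <- scalingAnalysis(profileSeries(imgs, "linear"))
#' scalingConstants(res)    # ~ (1, 0.8, 0.6, 0.4, 0.2)
#' @export
scalingAnalysis <- function(series, order = 3) {
  stopifnot(is(series, "PWMSeries"))
  ref <- referenceLevel(series)
  refFit <- fitReference(series[[ref]], order)
  lv <- c(ref, nonReferenceLevels(series))
  d <- numeric(length(lv)); err <- numeric(length(lv))
  d[1] <- 1; err[1] <- refFit@error
  for (i in seq_along(lv)[-1]) {
    o <- optimalScalingConstant(series[[lv[i]]], refFit)
    d[i] <- o$d; err[i] <- o$error
  }
  baseline <- lv / 100
  nonref <- seq_along(lv)[-1]
  rmse <- if (length(nonref)) sqrt(mean((d[nonref] - baseline[nonref])^2)) else 0
  new("ScalingResult", referenceFit = refFit, levels = lv, d = d,
      errors = err, baseline = baseline, linearityRMSE = rmse,
      flagged = lv[d < 0 | d > 1.5])
}

#' Rank cameras by linearity
#'
#' Orders a set of scaling-analysis results (one per camera) by their
#' linearity score, most linear first.
#'
#' @param results named list of \linkS4class{ScalingResult}, one per camera.
#' @return data.frame with columns camera, linearityRMSE, rank (1 = most
#'   linear), ordered by rank.
#' @export
rankCamerasByLinearity <- function(results) {
  if (is.null(names(results))) stop("'results' must be named by camera")
  rmse <- vapply(results, linearityRMSE, 0)
  ord <- order(rmse)
  data.frame(camera = names(results)[ord], linearityRMSE = unname(rmse[ord]),
             rank = seq_along(ord))
}
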