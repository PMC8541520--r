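#' @rdname accessors
setMethod("positions", "IntensityProfile", function(x) x@t)

#' @rdname accessors
setMethod("intensities", "IntensityProfile", function(x) x@y)

#' @rdname accessors
setMethod("pwmLevel", "IntensityProfile", function(x) x@pwm)

#' @rdname accessors
setMethod("fitOrder", "PolynomialFit", function(x) x@order)

#' @rdname accessors
setMethod("fitError", "PolynomialFit", function(x) x@error)

#' Coefficients of a polynomial fit
#'
#' Returns the fitted coefficients, lowest order first by default. Set
#' \code{highestFirst = TRUE} for the ordering used by tools that store
#' the leading coefficient first.
#'
#' @param object a \linkS4class{PolynomialFit}.
#' @param highestFirst reverse to highest-order-first.
#' @param ... ignored.
#' @return numeric vector of length \code{fitOrder(object) + 1}.
#' @export
setMethod("coef", "PolynomialFit", function(object, highestFirst = FALSE, ...) {
  if (highestFirst) rev(object@coeffs) else object@coeffs
})

#' Fitted values of a polynomial fit on its own grid
#'
#' @param object a \linkS4class{PolynomialFit}.
#' @param ... ignored.
#' @export
setMethod("fitted", "PolynomialFit", function(object, ...) object@fitted)

#' @rdname accessors
setMethod("pwmLevels", "PWMSeries", function(x)
  as.numeric(names(x@profiles)))

#' @rdname accessors
setMethod("referenceLevel", "PWMSeries", function(x) x@referenceLevel)

#' Extract one profile from a PWM series
#'
#' @param x a \linkS4class{PWMSeries}.
#' @param i a PWM level (matched numerically).
#' @param j,drop,... ignored.
#' @return an \linkS4class{IntensityProfile}.
#' @export
setMethod("[[", "PWMSeries", function(x, i, j, ...) {
  lv <- as.numeric(names(x@profiles))
  k <- which(abs(lv - as.numeric(i)) < 1e-9)
  if (length(k) != 1L)
    stop("no profile at PWM level ", i)
  x@profiles[[k]]
})

#' Number of profiles in a PWM series
#' @param x a \linkS4class{PWMSeries}.
#' @export
setMethod("length", "PWMSeries", function(x) length(x@profiles))

#' @rdname accessors
setMethod("scalingConstants", "ScalingResult", function(x)
  stats::setNames(x@d, x@levels))

#' @rdname accessors
setMethod("baselineConstants", "ScalingResult", function(x)
  stats::setNames(x@baseline, x@levels))

#' @rdname accessors
setMethod("scalingErrors", "ScalingResult", function(x)
  stats::setNames(x@errors, x@levels))

#' @rdname accessors
setMethod("linearityRMSE", "ScalingResult", function(x) x@linearityRMSE)

#' @rdname accessors
setMethod("bandVolumes", "DilutionFit", function(x) x@volumes)

#' @rdname accessors
setMethod("rSquared", "DilutionFit", function(x) x@r2)

#' @rdname accessors
setMethod("snr", "DilutionFit", function(x) x@snr)

setMethod("show", "CameraModel", function(object) {
  cat(sprintf(
    "CameraModel '%s': gain %.4g, gamma %.4g, offset %.4g, saturation %g, noise sigma %.4g\n",
    object@id, object@gain, object@gamma, object@offset, object@saturation,
    object@noiseSigma))
})

setMethod("show", "IlluminationField", function(object) {
  cat("IlluminationField: spatial polynomial of order",
      length(object@coeffs) - 1L, "\n  coefficients (low->high):",
      paste(signif(object@coeffs, 5), collapse = ", "), "\n")
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile: %d points on t in [0, 1], PWM %s\n",
              length(object@t),
              if (is.na(object@pwm)) "unknown" else format(object@pwm)))
  cat(sprintf("  brightness range [%.4g, %.4g] counts\n",
              min(object@y), max(object@y)))
})

setMethod("show", "PolynomialFit", function(object) {
  cat(sprintf("PolynomialFit: order %d, residual variance %.6g counts^2\n",
              object@order, object@error))
  cat("  coefficients (low->high):",
      paste(signif(object@coeffs, 6), collapse = ", "), "\n")
})

setMethod("show", "PWMSeries", function(object) {
  cat(sprintf("PWMSeries: %d levels (%s), reference %g, %d points/profile\n",
              length(object@profiles),
              paste(names(object@profiles), collapse = ", "),
              object@referenceLevel, length(object@profiles[[1L]]@t)))
})

setMethod("show", "ScalingResult", function(object) {
  cat("ScalingResult (optimal scaling constants vs the duty-100 reference)\n")
  df <- data.frame(pwm = object@levels, d = signif(object@d, 6),
                   baseline = object@baseline,
                   error = signif(object@errors, 6))
  print(df, row.names = FALSE)
  cat(sprintf("linearity RMSE vs pwm/100 baseline: %.6g\n",
              object@linearityRMSE))
  if (length(object@flagged))
    cat("  suspicious d outside [0, 1.5] at levels:",
        paste(object@flagged, collapse = ", "), "\n")
})

setMethod("show", "DilutionFit", function(object) {
  cat(sprintf(
    "DilutionFit: %d bands; slope %.6g, intercept %.6g, R^2 %.6g, SNR %s%s\n",
    length(object@volumes), object@slope, object@intercept, object@r2,
    format(object@snr), if (object@degenerate) " (degenerate)" else ""))
})

setMethod("show", "GelScene", function(object) {
  cat(sprintf(
    "GelScene: %d x %d px, %d lanes (concentrations %s), band peak %g on background %g%s\n",
    object@dim[1], object@dim[2], length(object@concentrations),
    paste(signif(object@concentrations, 3), collapse = ", "),
    object@bandPeak, object@background,
    if (nrow(object@corners)) ", with projective warp" else ""))
})
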