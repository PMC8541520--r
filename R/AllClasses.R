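#' @import methods
NULL

#' Parametric camera response model
#'
#' Describes how a (simulated) camera maps scene radiance to digital counts:
#' \code{counts = clip(gain * radiance^gamma + offset + noise, 0, saturation)}.
#' \code{gamma = 1} is an ideally linear sensor, the property the linearity
#' analyses score; gamma, offset and clipping are the distortions a real
#' camera may introduce.
#'
#' @slot id camera identifier used for provenance in reports.
#' @slot gain counts per unit radiance (> 0).
#' @slot gamma dimensionless response exponent (> 0); 1 = linear.
#' @slot offset additive counts (black level).
#' @slot saturation maximum representable count (255 for 8-bit, 65535 for
#'   16-bit).
#' @slot noiseSigma standard deviation of additive Gaussian read noise, in
#'   counts (>= 0).
#' @export
setClass("CameraModel",
  representation(
    id = "character",
    gain = "numeric",
    gamma = "numeric",
    offset = "numeric",
    saturation = "numeric",
    noiseSigma = "numeric"
  )
)

setValidity("CameraModel", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a non-empty string")
  for (s in c("gain", "gamma", "offset", "saturation", "noiseSigma")) {
    if (!isScalarNum(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msg)) return(msg)
  if (object@gain <= 0) msg <- c(msg, "'gain' must be > 0")
  if (object@gamma <= 0) msg <- c(msg, "'gamma' must be > 0")
  if (object@saturation <= 0) msg <- c(msg, "'saturation' must be > 0")
  if (object@noiseSigma < 0) msg <- c(msg, "'noiseSigma' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Spatial illumination field under PWM dimming
#'
#' Relative radiance across the test sheet as a polynomial in the normalized
#' position t in [0, 1], scaled proportionally by the PWM duty cycle:
#' \code{L(t; pwm) = (pwm/100) * poly(t)}. The LED is assumed exactly
#' proportional to duty cycle, so any departure from proportional image
#' brightness is attributed to the camera.
#'
#' @slot coeffs polynomial coefficients of the spatial profile, lowest order
#'   first; the polynomial must be non-negative on [0, 1].
#' @export
setClass("IlluminationField", representation(coeffs = "numeric"))

setValidity("IlluminationField", function(object) {
  if (length(object@coeffs) < 1L || !all(is.finite(object@coeffs)))
    return("'coeffs' must be a non-empty finite numeric vector")
  tt <- seq(0, 1, length.out = 1001L)
  if (min(polyvalAsc(object@coeffs, tt)) < 0)
    return("spatial radiance polynomial must be non-negative on [0, 1]")
  TRUE
})

#' Synthetic gel scene description
#'
#' Geometry and photometry of a simulated electrophoresis gel photograph: one
#' Gaussian band per lane whose peak amplitude (hence integrated volume) is
#' proportional to the lane's relative sample concentration, on a uniform
#' background, with optional additive Gaussian noise and an optional
#' projective warp defined by four corner points.
#'
#' @slot dim image rows, cols.
#' @slot concentrations relative concentrations, one per lane (all > 0).
#' @slot bandRow band center row (0-based pixel coordinate).
#' @slot bandSigmaRow,bandSigmaCol Gaussian band standard deviations in pixels.
#' @slot bandPeak peak amplitude, in counts, of a band at concentration 1.
#' @slot background uniform background level in counts.
#' @slot noiseSigma additive Gaussian noise sigma in counts.
#' @slot saturation maximum count of the simulated camera.
#' @slot corners 4 x 2 matrix of (x, y) corner points (top-left, top-right,
#'   bottom-right, bottom-left) for an optional projective warp, or a 0-row
#'   matrix for none.
#' @export
setClass("GelScene",
  representation(
    dim = "integer",
    concentrations = "numeric",
    bandRow = "numeric",
    bandSigmaRow = "numeric",
    bandSigmaCol = "numeric",
    bandPeak = "numeric",
    background = "numeric",
    noiseSigma = "numeric",
    saturation = "numeric",
    corners = "matrix"
  )
)

setValidity("GelScene", function(object) {
  msg <- character()
  if (length(object@dim) != 2L || any(object@dim < 1L))
    msg <- c(msg, "'dim' must be two positive integers (rows, cols)")
  if (length(object@concentrations) < 1L || any(object@concentrations <= 0))
    msg <- c(msg, "'concentrations' must all be strictly positive")
  if (object@bandSigmaRow <= 0 || object@bandSigmaCol <= 0)
    msg <- c(msg, "band sigmas must be > 0")
  if (object@bandPeak <= 0) msg <- c(msg, "'bandPeak' must be > 0")
  if (object@background < 0) msg <- c(msg, "'background' must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "'noiseSigma' must be >= 0")
  if (object@saturation <= 0) msg <- c(msg, "'saturation' must be > 0")
  if (nrow(object@corners) != 0L &&
      (nrow(object@corners) != 4L || ncol(object@corners) != 2L))
    msg <- c(msg, "'corners' must be a 4 x 2 matrix or empty")
  if (length(msg)) msg else TRUE
})

#' Normalized intensity profile
#'
#' A one-dimensional brightness trace y(t) taken across an image, with pixel
#' positions normalized to t in [0, 1] so cameras with different pixel counts
#' share a common domain.
#'
#' @slot t normalized positions; strictly increasing, t[1] = 0, t[N] = 1.
#' @slot y brightness in counts, same length as t.
#' @slot pwm PWM duty level the image was taken at (NA if unknown).
#' @slot meta provenance list (camera id, shot index, saturation fraction...).
#' @export
setClass("IntensityProfile",
  representation(t = "numeric", y = "numeric", pwm = "numeric", meta = "list")
)

setValidity("IntensityProfile", function(object) {
  msg <- character()
  n <- length(object@t)
  if (n < 2L) msg <- c(msg, "profile needs at least 2 points")
  if (length(object@y) != n) msg <- c(msg, "'t' and 'y' lengths differ")
  if (n >= 2L) {
    if (any(diff(object@t) <= 0)) msg <- c(msg, "'t' must be strictly increasing")
    if (abs(object@t[1]) > 1e-12 || abs(object@t[n] - 1) > 1e-12)
      msg <- c(msg, "'t' must span [0, 1]")
  }
  if (!all(is.finite(object@y))) msg <- c(msg, "'y' must be finite")
  if (length(object@pwm) != 1L) msg <- c(msg, "'pwm' must be a scalar (may be NA)")
  if (length(msg)) msg else TRUE
})

#' Polynomial fit of an intensity profile
#'
#' Ordinary least-squares polynomial fit on the monomial basis of t, scored by
#' the population variance of the residuals (divisor N). Coefficients are
#' stored lowest order first.
#'
#' @slot order polynomial order n (>= 1).
#' @slot coeffs n + 1 coefficients, lowest order first.
#' @slot t the fit grid (normalized positions).
#' @slot fitted fitted values on the fit grid.
#' @slot error population variance of the residuals, counts^2.
#' @export
setClass("PolynomialFit",
  representation(order = "integer", coeffs = "numeric", t = "numeric",
                 fitted = "numeric", error = "numeric")
)

setValidity("PolynomialFit", function(object) {
  msg <- character()
  if (object@order < 1L) msg <- c(msg, "'order' must be >= 1")
  if (length(object@coeffs) != object@order + 1L)
    msg <- c(msg, "length(coeffs) must equal order + 1")
  if (length(object@fitted) != length(object@t))
    msg <- c(msg, "'fitted' and 't' lengths differ")
  if (length(object@error) != 1L || object@error < 0)
    msg <- c(msg, "'error' must be a non-negative scalar")
  if (length(msg)) msg else TRUE
})

#' A brightness series across PWM levels
#'
#' Intensity profiles of the same scene photographed at several PWM duty
#' levels, sharing one normalized position grid. The duty-100 profile (taken
#' under the brightest lighting) is the reference all comparisons are made
#' against.
#'
#' @slot profiles named list of \linkS4class{IntensityProfile}, names are the
#'   PWM levels.
#' @slot referenceLevel the reference duty level (100).
#' @export
setClass("PWMSeries",
  representation(profiles = "list", referenceLevel = "numeric")
)

setValidity("PWMSeries", function(object) {
  msg <- character()
  if (length(object@profiles) < 1L) return("series has no profiles")
  if (!all(vapply(object@profiles, is, TRUE, "IntensityProfile")))
    return("all elements of 'profiles' must be IntensityProfile")
  lv <- suppressWarnings(as.numeric(names(object@profiles)))
  if (any(is.na(lv))) msg <- c(msg, "profile names must be numeric PWM levels")
  if (anyDuplicated(lv)) msg <- c(msg, "PWM levels must be distinct")
  if (!any(lv == object@referenceLevel))
    msg <- c(msg, sprintf("reference level %g missing from series",
                          object@referenceLevel))
  if (length(msg) == 0L) {
    t0 <- object@profiles[[1L]]@t
    same <- vapply(object@profiles, function(p)
      length(p@t) == length(t0) && max(abs(p@t - t0)) < 1e-12, TRUE)
    if (!all(same)) msg <- c(msg, "all profiles must share one t grid")
    if (any(lv < 0 | lv > 100)) msg <- c(msg, "PWM levels must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' Optimal scaling constants against the reference fit
#'
#' For each PWM level w the constant d_w minimizing the population variance of
#' \code{y_w - d * yhat_100(t)}, the error at the optimum, and the deviation of
#' d_w from the proportional baseline w/100. The root-mean-square of that
#' deviation over the non-reference levels is the scalar linearity score:
#' smaller means a more linear camera.
#'
#' @slot referenceFit \linkS4class{PolynomialFit} of the duty-100 profile.
#' @slot levels PWM levels, reference first.
#' @slot d optimal scaling constants, named by level (d at the reference is 1
#'   by construction).
#' @slot errors residual-variance error at the optimum, named by level.
#' @slot baseline the proportional constants level/100.
#' @slot linearityRMSE RMS deviation of d from the baseline over non-reference
#'   levels.
#' @slot flagged levels whose d fell outside [0, 1.5] (suspicious, not clipped).
#' @export
setClass("ScalingResult",
  representation(referenceFit = "PolynomialFit", levels = "numeric",
                 d = "numeric", errors = "numeric", baseline = "numeric",
                 linearityRMSE = "numeric", flagged = "numeric")
)

setValidity("ScalingResult", function(object) {
  n <- length(object@levels)
  if (length(object@d) != n || length(object@errors) != n ||
      length(object@baseline) != n)
    return("'d', 'errors' and 'baseline' must match 'levels' in length")
  if (any(object@errors < -1e-12)) return("errors must be non-negative")
  TRUE
})

#' Dilution-series regression result
#'
#' Ordinary least-squares regression of background-subtracted band volume on
#' relative concentration, with the coefficient of determination R^2 and the
#' derived signal-to-noise ratio SNR = R^2 / (1 - R^2) used as the
#' system-sensitivity index.
#'
#' @slot concentrations relative concentrations.
#' @slot volumes band volumes in counts.
#' @slot slope,intercept regression line volume = slope * concentration +
#'   intercept.
#' @slot r2 coefficient of determination in [0, 1].
#' @slot snr R^2 / (1 - R^2); Inf when r2 = 1 (flagged degenerate).
#' @slot degenerate TRUE when r2 is undefined (no volume variation) or snr is
#'   infinite.
#' @export
setClass("DilutionFit",
  representation(concentrations = "numeric", volumes = "numeric",
                 slope = "numeric", intercept = "numeric", r2 = "numeric",
                 snr = "numeric", degenerate = "logical")
)

setValidity("DilutionFit", function(object) {
  if (length(object@volumes) != length(object@concentrations))
    return("'volumes' and 'concentrations' lengths differ")
  if (!is.na(object@r2) && (object@r2 < -1e-12 || object@r2 > 1 + 1e-12))
    return("'r2' must lie in [0, 1]")
  TRUE
})
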