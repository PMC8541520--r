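#' Construct a PWM series from profiles
#'
#' @param profiles list of \linkS4class{IntensityProfile}, either named by
#'   PWM level or carrying their level in the \code{pwm} slot.
#' @param referenceLevel duty level used as the reference (100).
#' @return a \linkS4class{PWMSeries}.
#' @export
PWMSeries <- function(profiles, referenceLevel = 100) {
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, function(p) format(p@pwm), "")
  new("PWMSeries", profiles = profiles, referenceLevel = referenceLevel)
}

nonReferenceLevels <- function(series) {
  lv <- pwmLevels(series)
  lv[lv != referenceLevel(series)]
}

#' Reflectance-constancy check across brightness levels
#'
#' Tests whether the scene's reflectance profile is constant regardless of
#' illumination brightness: for each duty level w the fitted profile curve is
#' compared against the duty-100 reference fit scaled by the nominal constant
#' w/100. For a linear camera under proportional LED dimming the two agree;
#' the per-level maximum absolute deviation (and, as a smoother summary, the
#' deviation variance) quantifies departure. Curves are evaluated on a
#' 100-point grid; the scaled baseline is also tabulated on a coarse 10-point
#' grid for plotting as discrete markers over the solid fit curve.
#'
#' @param series a \linkS4class{PWMSeries}.
#' @param order polynomial order for the per-level fits (default 3).
#' @return list with \code{summary} (data.frame: pwm, constant, maxAbsDeviation,
#'   deviationVariance), \code{curves} (per-level data.frame of t, fit,
#'   scaledReference on the fine grid), \code{baselinePoints} (coarse-grid
#'   scaled reference values), and \code{fits}.
#' @export
reflectanceConstancy <- function(series, order = 3) {
  stopifnot(is(series, "PWMSeries"))
  lv <- nonReferenceLevels(series)
  if (any(lv > 100)) stop("PWM level above the reference 100 has no nominal constant")
  refFit <- fitPolynomial(series[[referenceLevel(series)]], order)
  tFine <- seq(0, 1, length.out = 100L)
  tCoarse <- seq(0, 1, length.out = 10L)
  refFine <- polyvalAsc(refFit@coeffs, tFine)
  curves <- list(); basePts <- list()
  summary <- data.frame(pwm = numeric(0), constant = numeric(0),
                        maxAbsDeviation = numeric(0),
                        deviationVariance = numeric(0))
  fits <- list()
  for (w in lv) {
    fw <- fitPolynomial(series[[w]], order)
    fits[[format(w)]] <- fw
    cst <- w / 100
    fitFine <- polyvalAsc(fw@coeffs, tFine)
    dev <- fitFine - cst * refFine
    curves[[format(w)]] <- data.frame(t = tFine, fit = fitFine,
                                      scaledReference = cst * refFine)
    basePts[[format(w)]] <- data.frame(t = tCoarse,
                                       scaledReference = cst *
                                         polyvalAsc(refFit@coeffs, tCoarse))
    summary <- rbind(summary, data.frame(pwm = w, constant = cst,
                                         maxAbsDeviation = max(abs(dev)),
                                         deviationVariance = popVar(dev)))
  }
  list(summary = summary, curves = curves, baselinePoints = basePts,
       referenceFit = refFit, fits = fits)
}

#' First-order slope versus PWM duty
#'
#' Fits each profile with a first-order polynomial and regresses the
#' resulting slope on the duty level (with intercept). For a radiometrically
#' linear camera under proportional dimming the slope is proportional to the
#' duty, so the regression R^2 is 1; curvature in slope-vs-PWM reveals a
#' nonlinear response.
#'
#' @param series a \linkS4class{PWMSeries} with at least two levels.
#' @return list with \code{slopes} (named by level), \code{slopeR2}, and
#'   \code{degenerate} (TRUE when all slopes are equal so R^2 is undefined).
#' @export
slopeVsPWM <- function(series) {
  stopifnot(is(series, "PWMSeries"))
  lv <- pwmLevels(series)
  if (length(lv) < 2L) stop("need at least 2 PWM levels")
  slopes <- vapply(lv, function(w) fitPolynomial(series[[w]], 1)@coeffs[2], 0)
  names(slopes) <- format(lv)
  if (popVar(slopes) < 1e-24 * max(1, mean(slopes)^2))
    return(list(slopes = slopes, slopeR2 = NA_real_, degenerate = TRUE))
  m <- lm(slopes ~ lv)
  r2 <- 1 - sum(residuals(m)^2) / sum((slopes - mean(slopes))^2)
  list(slopes = slopes, slopeR2 = r2, degenerate = FALSE)
}

#' Polynomial-order selection by error plateau
#'
#' Computes the residual-variance error for each duty level at every order
#' n = 1..maxOrder and recommends the smallest order after which the error
#' has plateaued at every level: the relative improvement
#' (e[n] - e[n + 1]) / e[n] falls below \code{plateauTol} for all levels (an
#' error already at numerical zero counts as plateaued). If no such order
#' exists, maxOrder is returned.
#'
#' @param series a \linkS4class{PWMSeries}.
#' @param maxOrder highest order tried (default 6).
#' @param plateauTol relative-improvement threshold (default 0.05).
#' @return list with \code{orderErrors} (levels x orders matrix) and
#'   \code{recommendedOrder}.
#' @export
orderSelection <- function(series, maxOrder = 6, plateauTol = 0.05) {
  stopifnot(is(series, "PWMSeries"))
  maxOrder <- as.integer(maxOrder)
  if (maxOrder < 1L) stop("'maxOrder' must be >= 1")
  npts <- length(series@profiles[[1L]]@t)
  if (maxOrder >= npts)
    stop("'maxOrder' must be smaller than the number of profile points")
  lv <- pwmLevels(series)
  E <- matrix(NA_real_, length(lv), maxOrder,
              dimnames = list(format(lv), paste0("n", seq_len(maxOrder))))
  scale <- numeric(length(lv))
  for (i in seq_along(lv)) {
    prof <- series[[lv[i]]]
    scale[i] <- max(popVar(prof@y), .Machine$double.eps)
    for (n in seq_len(maxOrder)) E[i, n] <- fitPolynomial(prof, n)@error
  }
  recommended <- maxOrder
  if (maxOrder > 1L) {
    for (n in seq_len(maxOrder - 1L)) {
      plateaued <- vapply(seq_along(lv), function(i) {
        en <- E[i, n]
        if (en <= 1e-10 * scale[i]) return(TRUE)  # already at numerical zero
        (en - E[i, n + 1L]) / en < plateauTol
      }, TRUE)
      if (all(plateaued)) { recommended <- n; break }
    }
  }
  list(orderErrors = E, recommendedOrder = recommended)
}

#' Full first-stage linearity report
#'
#' Bundles the three first-stage analyses — reflectance constancy, slope
#' versus PWM, and polynomial-order selection — into one report for a
#' brightness series.
#'
#' @param series a \linkS4class{PWMSeries}.
#' @param order fit order for the constancy check.
#' @param maxOrder highest order tried in order selection.
#' @param plateauTol plateau threshold for the recommended order.
#' @return list with components \code{constancy}, \code{slopes},
#'   \code{orders}.
#' @export
method1Report <- function(series, order = 3, maxOrder = 6, plateauTol = 0.05) {
  list(constancy = reflectanceConstancy(series, order),
       slopes = slopeVsPWM(series),
       orders = orderSelection(series, maxOrder, plateauTol))
}
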