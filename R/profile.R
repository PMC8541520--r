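#' Construct an intensity profile directly
#'
#' Mostly used internally and in tests; see \code{\link{extractProfile}} for
#' building profiles from images.
#'
#' @param t normalized positions (strictly increasing, spanning [0, 1]).
#' @param y brightness values in counts.
#' @param pwm PWM duty level (NA if unknown).
#' @param meta provenance list.
#' @return an \linkS4class{IntensityProfile}.
#' @export
IntensityProfile <- function(t, y, pwm = NA_real_, meta = list()) {
  new("IntensityProfile", t = as.numeric(t), y = as.numeric(y),
      pwm = as.numeric(pwm), meta = meta)
}

#' Extract a normalized intensity profile from an image
#'
#' Reduces an image to a 1-D brightness trace along the illumination-gradient
#' axis. With \code{axis = "columns"} (default) the profile value at column c
#' is the mean over rows of that column, which suppresses pixel noise; pixel
#' positions are normalized to t_i = i / (N - 1) so cameras with different
#' pixel counts share the [0, 1] domain.
#'
#' @param image numeric matrix (grayscale) or rows x cols x 3 array (RGB).
#' @param axis \code{"columns"} to profile along columns (mean over rows) or
#'   \code{"rows"} for the transpose.
#' @param channel for RGB input, one of "red", "green", "blue"; defaults to
#'   the green channel (green LED illumination). Requesting a channel on
#'   grayscale input is an error.
#' @param pwm duty level recorded in the profile.
#' @param cameraId,shot provenance tags.
#' @param saturation when supplied, the fraction of contributing pixels equal
#'   to this value is stored in \code{meta$saturationFraction} and a warning
#'   is emitted if it exceeds 1% (saturated pixels are kept, not excluded).
#' @return an \linkS4class{IntensityProfile}.
#' @examples
#' img <- matrix(rep(0:255, each = 4), nrow = 4)   # identity gradient
#' p <- extractProfile(img)
#' range(intensities(p))
#' @export
extractProfile <- function(image, axis = c("columns", "rows"), channel = NULL,
                           pwm = NA_real_, cameraId = NA_character_,
                           shot = NA_integer_, saturation = NULL) {
  axis <- match.arg(axis)
  if (length(image) == 0L) stop("empty image")
  if (is.array(image) && length(dim(image)) == 3L) {
    channel <- channel %||% "green"
    k <- match(match.arg(channel, c("red", "green", "blue")),
               c("red", "green", "blue"))
    image <- image[, , k]
  } else if (is.matrix(image)) {
    if (!is.null(channel))
      stop("channel selection requested on a grayscale image")
  } else stop("'image' must be a matrix or a rows x cols x 3 array")
  if (axis == "rows") image <- t(image)
  n <- ncol(image)
  if (n < 2L) stop("image must have at least 2 pixels along the profile axis")
  y <- colMeans(image)
  t <- (seq_len(n) - 1) / (n - 1)
  meta <- list(camera = cameraId, shot = shot)
  if (!is.null(saturation)) {
    frac <- mean(image >= saturation)
    meta$saturationFraction <- frac
    if (frac > 0.01)
      warning(sprintf("%.1f%% of contributing pixels are saturated; %s",
                      100 * frac,
                      "profile and fits may understate brightness"))
  }
  IntensityProfile(t, y, pwm = pwm, meta = meta)
}

#' Fit a polynomial to an intensity profile
#'
#' Ordinary least squares on the monomial basis of t (the domain [0, 1] keeps
#' the basis well conditioned at the orders used here, <= 6). The fit error
#' is the population variance (divisor N) of the residuals y - yhat.
#'
#' @param profile an \linkS4class{IntensityProfile}.
#' @param order polynomial order n >= 1; must be smaller than the number of
#'   points.
#' @return a \linkS4class{PolynomialFit} with coefficients lowest order
#'   first.
#' @examples
#' p <- IntensityProfile(seq(0, 1, 0.1), 2 + 3 * seq(0, 1, 0.1))
#' coef(fitPolynomial(p, 1))   # ~ (2, 3)
#' @export
fitPolynomial <- function(profile, order) {
  stopifnot(is(profile, "IntensityProfile"))
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be >= 1")
  n <- length(profile@t)
  if (order >= n)
    stop("underdetermined fit: order (", order,
         ") must be smaller than the number of points (", n, ")")
  X <- outer(profile@t, 0:order, `^`)
  fit <- lm.fit(X, profile@y)
  coeffs <- unname(fit$coefficients)
  coeffs[is.na(coeffs)] <- 0
  yhat <- drop(X %*% coeffs)
  new("PolynomialFit", order = order, coeffs = coeffs, t = profile@t,
      fitted = yhat, error = popVar(profile@y - yhat))
}

#' Evaluate a polynomial fit at query positions
#'
#' Horner evaluation of the fitted polynomial. Queries outside [0, 1] are
#' extrapolation beyond the normalized image domain; they are permitted but
#' flagged with a warning.
#'
#' @param fit a \linkS4class{PolynomialFit}.
#' @param t positions.
#' @return fitted values at \code{t}.
#' @export
evaluateFit <- function(fit, t) {
  stopifnot(is(fit, "PolynomialFit"))
  if (any(t < -1e-12 | t > 1 + 1e-12))
    warning("evaluating the fit outside [0, 1] (extrapolation)")
  polyvalAsc(fit@coeffs, t)
}

#' Residual-variance error of a fit against a profile
#'
#' The population variance (divisor N) of y - yhat on the shared t grid.
#' Because variance subtracts the residual mean, a constant residual offset
#' contributes nothing to this metric; that blind spot is intentional and
#' documented — the metric scores shape agreement, not absolute level.
#'
#' @param profile an \linkS4class{IntensityProfile}.
#' @param fit a \linkS4class{PolynomialFit} on the same t grid.
#' @return scalar error in counts^2.
#' @export
residualError <- function(profile, fit) {
  stopifnot(is(profile, "IntensityProfile"), is(fit, "PolynomialFit"))
  if (length(profile@t) != length(fit@t) ||
      max(abs(profile@t - fit@t)) > 1e-12)
    stop("profile and fit are not on the same t grid")
  popVar(profile@y - fit@fitted)
}
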