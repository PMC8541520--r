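#' Construct a camera response model
#'
#' @param id camera identifier (used for provenance in reports).
#' @param gain counts per unit radiance.
#' @param gamma response exponent; 1 simulates an ideally linear sensor.
#' @param offset black-level offset in counts.
#' @param saturation maximum count (255 for 8-bit images, 65535 for 16-bit).
#' @param noiseSigma Gaussian read-noise standard deviation in counts.
#' @return a \linkS4class{CameraModel}.
#' @examples
#' cam <- CameraModel("linear", gain = 220, gamma = 1)
#' cam
#' @export
CameraModel <- function(id, gain = 200, gamma = 1, offset = 0,
                        saturation = 255, noiseSigma = 0) {
  new("CameraModel", id = as.character(id), gain = gain, gamma = gamma,
      offset = offset, saturation = saturation, noiseSigma = noiseSigma)
}

#' Construct a PWM-dimmed illumination field
#'
#' The default spatial profile is a monotone cubic in the normalized position,
#' emulating the smoothly non-uniform lighting of a real LED + diffuser rig
#' (and exercising polynomial-order selection up to the cubic term).
#'
#' @param coeffs spatial polynomial coefficients, lowest order first; the
#'   polynomial must be non-negative on [0, 1].
#' @return an \linkS4class{IlluminationField}.
#' @export
IlluminationField <- function(coeffs = c(0.6, 0.5, -0.35, 0.25)) {
  new("IlluminationField", coeffs = coeffs)
}

#' Relative radiance of an illumination field
#'
#' @param field an \linkS4class{IlluminationField}.
#' @param t normalized positions in [0, 1].
#' @param pwm duty level in [0, 100].
#' @return radiance values (relative units), \code{(pwm/100) * poly(t)}.
#' @export
fieldRadiance <- function(field, t, pwm = 100) {
  stopifnot(is(field, "IlluminationField"))
  if (!isScalarNum(pwm) || pwm < 0 || pwm > 100)
    stop("'pwm' must lie in [0, 100]")
  (pwm / 100) * polyvalAsc(field@coeffs, t)
}

#' Simulate one brightness-gradient test-sheet image
#'
#' Generates a seeded synthetic photograph of a uniformly reflective test
#' sheet under the given illumination at one PWM level. The image varies only
#' along columns (rows are noisy replicates):
#' \code{pixel(r, c) = clip(gain * L(t_c)^gamma + offset + noise, 0,
#' saturation)} with \code{t_c = c / (cols - 1)}.
#'
#' @param camera a \linkS4class{CameraModel}.
#' @param field an \linkS4class{IlluminationField}.
#' @param pwm duty level in [0, 100].
#' @param dim image size as c(rows, cols).
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   images.
#' @return numeric matrix of counts (not quantized; quantization happens only
#'   on file output).
#' @examples
#' cam <- CameraModel("linear", gain = 220, gamma = 1)
#' img <- simulateGradientImage(cam, IlluminationField(), pwm = 100,
#'                              dim = c(8, 64), seed = 1)
#' dim(img)
#' @export
simulateGradientImage <- function(camera, field, pwm, dim = c(64L, 256L),
                                  seed = 1L) {
  stopifnot(is(camera, "CameraModel"), is(field, "IlluminationField"))
  dim <- as.integer(dim)
  if (length(dim) != 2L || any(dim < 1L))
    stop("'dim' must be two positive integers (rows, cols)")
  if (!isScalarNum(pwm) || pwm < 0 || pwm > 100)
    stop("'pwm' must lie in [0, 100]")
  nr <- dim[1]; nc <- dim[2]
  tc <- if (nc == 1L) 0 else (seq_len(nc) - 1) / (nc - 1)
  L <- fieldRadiance(field, tc, pwm)
  signal <- camera@gain * L^camera@gamma + camera@offset
  img <- matrix(signal, nrow = nr, ncol = nc, byrow = TRUE)
  if (camera@noiseSigma > 0) {
    eps <- withSeed(seed, matrix(rnorm(nr * nc, 0, camera@noiseSigma), nr, nc))
    img <- img + eps
  }
  clipCounts(img, 0, camera@saturation)
}

#' Simulate a full PWM brightness series
#'
#' One gradient image per duty level, sharing camera and illumination
#' parameters. The duty-100 reference level must be included, mirroring the
#' acquisition order (100, 80, 60, 40, 20) used when evaluating cameras.
#' Per-level seeds are derived deterministically from the base seed so the
#' series is reproducible level by level.
#'
#' @inheritParams simulateGradientImage
#' @param levels distinct duty levels in [0, 100]; must contain 100.
#' @return named list of images, names are the PWM levels.
#' @export
simulatePWMSeries <- function(camera, field, levels = c(100, 80, 60, 40, 20),
                              dim = c(64L, 256L), seed = 1L) {
  levels <- as.numeric(levels)
  if (anyDuplicated(levels)) stop("PWM levels must be distinct")
  if (any(levels < 0 | levels > 100)) stop("PWM levels must lie in [0, 100]")
  if (!any(levels == 100)) stop("the reference level 100 must be included")
  out <- lapply(levels, function(lv)
    simulateGradientImage(camera, field, lv, dim,
                          seed = deriveSeed(seed, round(lv * 1000))))
  names(out) <- as.character(levels)
  out
}

#' Reduce a series of gradient images to a PWMSeries of profiles
#'
#' Convenience wrapper: extracts a normalized intensity profile from every
#' image of \code{\link{simulatePWMSeries}} output (or any named list of
#' images keyed by PWM level) and bundles them.
#'
#' @param images named list of images, names are PWM levels.
#' @param cameraId provenance tag stored in each profile.
#' @param saturation if given, the fraction of saturated pixels is recorded
#'   per profile and a warning is emitted when it exceeds 1%.
#' @param ... passed to \code{\link{extractProfile}}.
#' @return a \linkS4class{PWMSeries}.
#' @export
profileSeries <- function(images, cameraId = NA_character_,
                          saturation = NULL, ...) {
  if (is.null(names(images))) stop("'images' must be named by PWM level")
  profs <- lapply(names(images), function(nm)
    extractProfile(images[[nm]], pwm = as.numeric(nm), cameraId = cameraId,
                   saturation = saturation, ...))
  names(profs) <- names(images)
  new("PWMSeries", profiles = profs, referenceLevel = 100)
}
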