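#' Construct a synthetic gel scene
#'
#' Describes a simulated electrophoresis gel photograph: one Gaussian band
#' per lane, all at the same migration row, with peak amplitude proportional
#' to the lane's relative concentration. Defaults follow the five-step
#' dilution series 1, 1/2, 1/5, 1/10, 1/20 commonly used to probe a
#' gel-document system's sensitivity.
#'
#' @param dim image size c(rows, cols).
#' @param concentrations relative concentrations, one lane each.
#' @param bandRow band center row (0-based); defaults to mid-height.
#' @param bandSigmaRow,bandSigmaCol band Gaussian sigmas in pixels.
#' @param bandPeak peak amplitude in counts at concentration 1.
#' @param background uniform background counts.
#' @param noiseSigma additive Gaussian noise sigma in counts.
#' @param saturation maximum count.
#' @param corners optional 4 x 2 (x, y) corner matrix describing where the
#'   gel rectangle sits on the output canvas; when given the rendered gel is
#'   projectively warped onto that quad (emulating an oblique photograph) and
#'   the corners are recorded for later rectification.
#' @return a \linkS4class{GelScene}.
#' @export
GelScene <- function(dim = c(120L, 360L),
                     concentrations = c(1, 1/2, 1/5, 1/10, 1/20),
                     bandRow = NULL, bandSigmaRow = 6, bandSigmaCol = 8,
                     bandPeak = 150, background = 20, noiseSigma = 0,
                     saturation = 255, corners = NULL) {
  dim <- as.integer(dim)
  if (is.null(bandRow)) bandRow <- (dim[1] - 1) / 2
  if (is.null(corners)) {
    corners <- matrix(numeric(0), 0, 2)
  } else {
    corners <- checkQuad(corners)
  }
  scene <- new("GelScene", dim = dim, concentrations = concentrations,
               bandRow = bandRow, bandSigmaRow = bandSigmaRow,
               bandSigmaCol = bandSigmaCol, bandPeak = bandPeak,
               background = background, noiseSigma = noiseSigma,
               saturation = saturation, corners = corners)
  if (background + bandPeak * max(concentrations) > saturation)
    warning("brightest band exceeds saturation; volumes will be clipped ",
            "and no longer proportional to concentration")
  scene
}

## lane center columns (0-based), lanes evenly spaced across the width
laneCenters <- function(scene) {
  n <- length(scene@concentrations)
  nc <- scene@dim[2]
  (seq_len(n) - 0.5) / n * nc - 0.5
}

#' Band regions of interest for a gel scene
#'
#' Rectangles (0-based, half-open) covering each band out to
#' \code{extent} sigmas, in the unwarped gel frame — the frame recovered by
#' \code{\link{rectifyImage}} when the scene was warped.
#'
#' @param scene a \linkS4class{GelScene}.
#' @param extent half-width of the ROI in band sigmas.
#' @return data.frame with columns lane, row0, col0, row1, col1,
#'   concentration.
#' @export
sceneROIs <- function(scene, extent = 4) {
  cc <- laneCenters(scene)
  r0 <- floor(scene@bandRow - extent * scene@bandSigmaRow)
  r1 <- ceiling(scene@bandRow + extent * scene@bandSigmaRow) + 1
  data.frame(
    lane = seq_along(cc),
    row0 = as.integer(r0),
    col0 = as.integer(floor(cc - extent * scene@bandSigmaCol)),
    row1 = as.integer(r1),
    col1 = as.integer(ceiling(cc + extent * scene@bandSigmaCol) + 1),
    concentration = scene@concentrations
  )
}

#' Render a synthetic gel image with known ground truth
#'
#' Draws one 2-D Gaussian band per lane, peak amplitude
#' \code{bandPeak * concentration}, on the uniform background, adds seeded
#' Gaussian noise, clips to the camera range, and (when corners are set)
#' applies the projective warp last. The returned ground-truth volumes are
#' the analytic Gaussian integrals \code{2 * pi * A * sigmaRow * sigmaCol},
#' excluding background and noise — exactly proportional to the
#' concentrations by construction.
#'
#' @param scene a \linkS4class{GelScene}.
#' @param seed integer seed for the noise field.
#' @return list with elements \code{image} (numeric matrix), \code{volumes}
#'   (ground-truth band volumes), \code{rois} (band rectangles in the
#'   unwarped frame, see \code{\link{sceneROIs}}), and \code{corners} (the
#'   recorded warp quad, or NULL).
#' @examples
#' g <- simulateGelImage(GelScene(noiseSigma = 0), seed = 1)
#' round(g$volumes / g$volumes[1], 3)   # 1, 0.5, 0.2, 0.1, 0.05
#' @export
simulateGelImage <- function(scene, seed = 1L) {
  stopifnot(is(scene, "GelScene"))
  nr <- scene@dim[1]; nc <- scene@dim[2]
  cc <- laneCenters(scene)
  n <- length(cc)
  laneHalf <- nc / n / 2
  ## bands must fit inside their lane and the image (out to 4 sigma)
  if (scene@bandRow - 4 * scene@bandSigmaRow < 0 ||
      scene@bandRow + 4 * scene@bandSigmaRow > nr - 1)
    stop("band overlaps the image top/bottom edge")
  if (4 * scene@bandSigmaCol > laneHalf)
    stop("band overlaps lane boundaries; reduce bandSigmaCol or lane count")
  rows <- 0:(nr - 1); cols <- 0:(nc - 1)
  gRow <- exp(-((rows - scene@bandRow)^2) / (2 * scene@bandSigmaRow^2))
  img <- matrix(scene@background, nr, nc)
  for (i in seq_len(n)) {
    gCol <- exp(-((cols - cc[i])^2) / (2 * scene@bandSigmaCol^2))
    img <- img + (scene@bandPeak * scene@concentrations[i]) *
      outer(gRow, gCol)
  }
  if (scene@noiseSigma > 0) {
    img <- img + withSeed(seed,
      matrix(rnorm(nr * nc, 0, scene@noiseSigma), nr, nc))
  }
  img <- clipCounts(img, 0, scene@saturation)
  corners <- NULL
  if (nrow(scene@corners)) {
    corners <- scene@corners
    outDim <- c(max(ceiling(corners[, 2])) + 8L, max(ceiling(corners[, 1])) + 8L)
    img <- warpToQuad(img, corners, outDim = outDim, fill = 0)
  }
  volumes <- 2 * pi * scene@bandPeak * scene@concentrations *
    scene@bandSigmaRow * scene@bandSigmaCol
  list(image = img, volumes = volumes, rois = sceneROIs(scene),
       corners = corners)
}
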