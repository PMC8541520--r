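#' Read and write grayscale images in counts
#'
#' Thin wrappers over the png and tiff readers keeping the package's
#' convention: images are numeric matrices in integer counts (0..saturation),
#' rows x cols. PNG carries 8-bit output, TIFF 16-bit. RGB files are reduced
#' on read by selecting a channel (default green) unless \code{channel =
#' "all"}, which returns the full array.
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @param channel for RGB files: "red", "green", "blue", or "all".
#' @return numeric matrix (or array for \code{channel = "all"}) in counts,
#'   plus attribute \code{saturation}.
#' @export
readImageGray <- function(path, channel = "green") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    sat <- 255
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    sat <- 65535
  } else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3L && channel != "all") {
    k <- match(match.arg(channel, c("red", "green", "blue")),
               c("red", "green", "blue"))
    img <- img[, , k]
  }
  img <- img * sat
  attr(img, "saturation") <- sat
  img
}

#' @rdname readImageGray
#' @param image numeric matrix in counts.
#' @param bitDepth 8 (PNG) or 16 (TIFF).
#' @export
writeImageGray <- function(image, path, bitDepth = 8) {
  sat <- 2^bitDepth - 1
  scaled <- clipCounts(image / sat, 0, 1)
  if (bitDepth == 8) {
    png::writePNG(scaled, target = path)
  } else if (bitDepth == 16) {
    tiff::writeTIFF(scaled, where = path, bits.per.sample = 16L)
  } else stop("'bitDepth' must be 8 or 16")
  invisible(path)
}

#' Read a band ROI annotation file
#'
#' CSV with columns lane, row0, col0, row1, col1, concentration; rectangles
#' are 0-based and half-open.
#'
#' @param path CSV path.
#' @return data.frame in the \code{\link{quantifyGel}} layout.
#' @export
readROIFile <- function(path) {
  d <- read.csv(path)
  need <- c("lane", "row0", "col0", "row1", "col1", "concentration")
  if (!all(need %in% names(d)))
    stop("ROI file must have columns ", paste(need, collapse = ", "))
  if (any(d$row0 >= d$row1) || any(d$col0 >= d$col1))
    stop("ROI file has empty rectangles (need row0 < row1, col0 < col1)")
  d[need]
}

#' Read a corner annotation file
#'
#' CSV with columns corner (tl, tr, br, bl), x, y; coordinates are 0-based
#' pixels (x = column, y = row).
#'
#' @param path CSV path.
#' @return 4 x 2 matrix ordered top-left, top-right, bottom-right,
#'   bottom-left.
#' @export
readCornerFile <- function(path) {
  d <- read.csv(path)
  if (!all(c("corner", "x", "y") %in% names(d)))
    stop("corner file must have columns corner, x, y")
  ord <- match(c("tl", "tr", "br", "bl"), d$corner)
  if (any(is.na(ord))) stop("corner file must label corners tl, tr, br, bl")
  as.matrix(d[ord, c("x", "y")])
}

#' Recorded alternating-shot experiments
#'
#' A small bundled table of per-shot dilution-series R^2 values and the ranks
#' recorded for four alternating-shot experiments comparing a DSLR camera and
#' two open-platform board cameras (AR0130, IMX179) on electrophoresis gels.
#' Used as a worked example for \code{\link{rankExperiment}}.
#'
#' @return data.frame with columns experiment, shot, camera, r2,
#'   recordedRank.
#' @examples
#' ex <- recordedRankExperiments()
#' rankExperiment(ex$r2[ex$experiment == 1])$ranks
#' @export
recordedRankExperiments <- function() {
  read.csv(system.file("extdata", "alternating_shot_r2.csv",
                       package = "gelimetry"))
}
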