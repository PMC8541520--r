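#' Solve a 3 x 3 homography from four point correspondences
#'
#' Computes the projective map H (with H[3,3] fixed to 1) such that
#' \code{dst ~ H %*% src} in homogeneous coordinates, from exactly four point
#' pairs: eight unknowns, eight equations, solved as a dense linear system.
#' Coordinates are (x, y) with x = column, y = row, 0-based.
#'
#' @param src,dst 4 x 2 matrices of (x, y) points.
#' @return a 3 x 3 matrix, normalized so the bottom-right entry is 1.
#' @export
solveHomography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!all(dim(src) == c(4L, 2L)) || !all(dim(dst) == c(4L, 2L)))
    stop("'src' and 'dst' must be 4 x 2 matrices of (x, y) points")
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]
    u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e)
    stop("degenerate corner configuration: ", conditionMessage(e)))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

## map (x, y) points through a homography; pts is n x 2
applyHomography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

## check a quad (tl, tr, br, bl) is convex with no three collinear corners
checkQuad <- function(quad) {
  quad <- as.matrix(quad)
  if (!all(dim(quad) == c(4L, 2L))) stop("corner quad must be 4 x 2")
  cr <- numeric(4)
  for (i in 1:4) {
    a <- quad[i, ]; b <- quad[(i %% 4) + 1, ]; c <- quad[((i + 1) %% 4) + 1, ]
    cr[i] <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  scale2 <- max(abs(quad))^2
  if (any(abs(cr) < 1e-9 * max(scale2, 1)) || length(unique(sign(cr))) != 1L)
    stop("corner quad is degenerate or non-convex")
  invisible(quad)
}

## bilinear sample of matrix 'img' at 0-based (x, y); out-of-range -> fill
bilinearSample <- function(img, x, y, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  ## clamp neighbour indices so out-of-range samples stay addressable; the
  ## 'ok' mask overwrites them with the fill value afterwards
  x1 <- pmin(pmax(x0 + 1, 0), nc - 1); y1 <- pmin(pmax(y0 + 1, 0), nr - 1)
  xs0 <- pmin(pmax(x0, 0), nc - 1); ys0 <- pmin(pmax(y0, 0), nr - 1)
  idx <- function(yy, xx) img[cbind(yy + 1, xx + 1)]
  v <- (1 - fx) * (1 - fy) * idx(ys0, xs0) +
       fx       * (1 - fy) * idx(ys0, x1) +
       (1 - fx) * fy       * idx(y1, xs0) +
       fx       * fy       * idx(y1, x1)
  v[!ok] <- fill
  v
}

## resample 'img' onto an outDim = c(rows, cols) canvas through homography
## Hmap, where Hmap sends destination (x, y) to source (x, y)
resampleThrough <- function(img, Hmap, outDim, fill = 0) {
  nr <- outDim[1]; nc <- outDim[2]
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  sp <- applyHomography(Hmap, cbind(xs, ys))
  matrix(bilinearSample(img, sp[, 1], sp[, 2], fill = fill), nr, nc)
}

## corner quad of a rows x cols image in (x, y), order tl, tr, br, bl
imageCornerQuad <- function(dim) {
  nr <- dim[1]; nc <- dim[2]
  rbind(c(0, 0), c(nc - 1, 0), c(nc - 1, nr - 1), c(0, nr - 1))
}

#' Rectify a perspective-distorted image from four corner points
#'
#' Maps the quadrilateral delimited by \code{quad} (order top-left, top-right,
#' bottom-right, bottom-left, (x, y) 0-based pixel coordinates) onto an
#' upright \code{width} x \code{height} rectangle using the exact 4-point
#' homography and bilinear resampling. This puts gel photographs taken at
#' different geometries and pixel counts into a common pixel frame before
#' band quantification.
#'
#' @param image numeric matrix (grayscale counts).
#' @param quad 4 x 2 corner matrix.
#' @param width,height target rectangle size in pixels.
#' @param fill value for target pixels that map outside the source image.
#' @return a \code{height} x \code{width} numeric matrix.
#' @export
rectifyImage <- function(image, quad, width, height, fill = 0) {
  checkQuad(quad)
  if (width < 1 || height < 1) stop("target size must be positive")
  dstRect <- rbind(c(0, 0), c(width - 1, 0), c(width - 1, height - 1),
                   c(0, height - 1))
  Hmap <- solveHomography(dstRect, as.matrix(quad))  # dest -> source
  resampleThrough(image, Hmap, c(height, width), fill = fill)
}

#' Warp an image onto a quadrilateral (inverse of rectification)
#'
#' Places the full source image onto the quadrilateral \code{quad} of an
#' \code{outDim} canvas, simulating a photograph taken at an oblique
#' geometry. \code{rectifyImage} with the same quad recovers the original
#' up to interpolation error.
#'
#' @param image numeric matrix.
#' @param quad 4 x 2 corner matrix on the output canvas (tl, tr, br, bl).
#' @param outDim output canvas size c(rows, cols); defaults to the input size.
#' @param fill background value outside the quad.
#' @return numeric matrix of size \code{outDim}.
#' @export
warpToQuad <- function(image, quad, outDim = dim(image), fill = 0) {
  checkQuad(quad)
  srcRect <- imageCornerQuad(dim(image))
  Hmap <- solveHomography(as.matrix(quad), srcRect)  # dest -> source
  resampleThrough(image, Hmap, outDim, fill = fill)
}
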