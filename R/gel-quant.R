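#' Band volume by background-subtracted densitometry
#'
#' Integrates a band's intensity over a rectangular region of interest after
#' subtracting a local background. The background is the median of the
#' border frame of the stated width surrounding the ROI (robust to the band's
#' own tails and to speckle); negative background-subtracted pixels are
#' clamped to zero before summation. Rectangles are 0-based and half-open:
#' rows \code{row0 <= r < row1}, columns \code{col0 <= c < col1}.
#'
#' @param image numeric matrix of counts.
#' @param roi rectangle as c(row0, col0, row1, col1) or a one-row data.frame
#'   with those columns.
#' @param borderWidth width in pixels of the background frame (>= 1).
#' @param background optional externally fixed background level; when given
#'   the border median is skipped (useful for partition-additivity checks).
#' @return scalar band volume in counts.
#' @examples
#' img <- matrix(40, 50, 50)
#' bandVolume(img, c(10, 10, 30, 30))   # uniform image -> 0
#' @export
bandVolume <- function(image, roi, borderWidth = 3, background = NULL) {
  if (is.data.frame(roi)) roi <- c(roi$row0[1], roi$col0[1], roi$row1[1], roi$col1[1])
  roi <- as.numeric(roi)
  if (length(roi) != 4L) stop("'roi' must be c(row0, col0, row1, col1)")
  r0 <- roi[1]; c0 <- roi[2]; r1 <- roi[3]; c1 <- roi[4]
  nr <- nrow(image); nc <- ncol(image)
  if (r0 < 0 || c0 < 0 || r1 > nr || c1 > nc || r0 >= r1 || c0 >= c1)
    stop("ROI out of image bounds or empty")
  inner <- image[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  if (is.null(background)) {
    if (borderWidth < 1) stop("'borderWidth' must be >= 1")
    R0 <- max(r0 - borderWidth, 0); C0 <- max(c0 - borderWidth, 0)
    R1 <- min(r1 + borderWidth, nr); C1 <- min(c1 + borderWidth, nc)
    if (R0 == r0 && C0 == c0 && R1 == r1 && C1 == c1)
      stop("ROI plus border exceeds the image; no background frame available")
    outer <- image[(R0 + 1):R1, (C0 + 1):C1, drop = FALSE]
    mask <- matrix(TRUE, nrow(outer), ncol(outer))
    mask[(r0 - R0 + 1):(r1 - R0), (c0 - C0 + 1):(c1 - C0)] <- FALSE
    background <- median(outer[mask])
  }
  sum(pmax(inner - background, 0))
}

#' Automatic band detection in a rectified gel image
#'
#' Optional helper locating lanes from the column intensity profile: the
#' background-subtracted column sums are smoothed with a moving-average
#' window and local maxima with prominence above a fraction of the dynamic
#' range become lane centers. Intended as a convenience; curated ROI files
#' remain the primary quantification path.
#'
#' @param image numeric matrix.
#' @param smoothWindow moving-average window in pixels (odd; default 5).
#' @param minProminence minimum peak prominence as a fraction of the profile
#'   dynamic range (default 0.05).
#' @return integer vector of detected band center columns (0-based).
#' @export
findBands <- function(image, smoothWindow = 5, minProminence = 0.05) {
  prof <- colSums(image - median(image))
  k <- max(1L, as.integer(smoothWindow))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- stats::filter(prof, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- prof[is.na(sm)]
  sm <- as.numeric(sm)
  rng <- diff(range(sm))
  if (rng <= 0) return(integer(0))
  n <- length(sm)
  peaks <- which(sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf))
  keep <- vapply(peaks, function(p) {
    ## prominence: height above the higher of the two flanking minima
    left <- if (p > 1) min(sm[1:(p - 1)]) else min(sm)
    right <- if (p < n) min(sm[(p + 1):n]) else min(sm)
    (sm[p] - max(left, right)) >= minProminence * rng
  }, TRUE)
  as.integer(peaks[keep] - 1L)
}

#' Signal-to-noise ratio from the coefficient of determination
#'
#' The sensitivity index SNR = R^2 / (1 - R^2); its inverse is
#' \code{\link{r2FromSNR}}. Monotone increasing on [0, 1); R^2 = 1 maps to
#' Inf.
#'
#' @param r2 coefficient(s) of determination in [0, 1].
#' @return SNR value(s).
#' @export
snrFromR2 <- function(r2) {
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("'r2' must lie in [0, 1]")
  ifelse(r2 == 1, Inf, r2 / (1 - r2))
}

#' @rdname snrFromR2
#' @param snr signal-to-noise ratio(s) >= 0.
#' @export
r2FromSNR <- function(snr) {
  if (any(snr < 0, na.rm = TRUE)) stop("'snr' must be >= 0")
  ifelse(is.infinite(snr), 1, snr / (1 + snr))
}

#' Regress band volumes on the dilution series
#'
#' Ordinary least-squares line volume = slope * concentration + intercept,
#' with the coefficient of determination R^2 = 1 - RSS/TSS and the derived
#' sensitivity index SNR = R^2 / (1 - R^2). A perfectly proportional system
#' gives R^2 = 1 (SNR reported as Inf and flagged degenerate, treated as the
#' maximum in rankings); identical volumes leave R^2 undefined (NA,
#' degenerate).
#'
#' @param volumes band volumes in counts (>= 3 values).
#' @param concentrations distinct relative concentrations, same length.
#' @return a \linkS4class{DilutionFit}.
#' @examples
#' conc <- c(1, 1/2, 1/5, 1/10, 1/20)
#' dilutionRegression(1000 * conc, conc)
#' @export
dilutionRegression <- function(volumes, concentrations) {
  if (length(volumes) < 3L) stop("need at least 3 points")
  if (length(volumes) != length(concentrations))
    stop("'volumes' and 'concentrations' lengths differ")
  if (anyDuplicated(concentrations)) stop("concentrations must be distinct")
  if (popVar(volumes) <= .Machine$double.eps * max(1, mean(volumes)^2)) {
    return(new("DilutionFit", concentrations = concentrations,
               volumes = volumes, slope = 0, intercept = mean(volumes),
               r2 = NA_real_, snr = NA_real_, degenerate = TRUE))
  }
  m <- lm(volumes ~ concentrations)
  rss <- sum(residuals(m)^2)
  tss <- sum((volumes - mean(volumes))^2)
  r2 <- max(0, min(1, 1 - rss / tss))
  ## guard against r2 == 1 only up to round-off
  if (rss <= 1e-20 * tss) r2 <- 1
  s <- snrFromR2(r2)
  new("DilutionFit", concentrations = concentrations, volumes = volumes,
      slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
      r2 = r2, snr = s, degenerate = is.infinite(s))
}

#' Quantify a dilution-series gel image
#'
#' Measures every band volume from a ROI table and regresses the volumes on
#' the concentrations.
#'
#' @param image numeric matrix (rectified gel image).
#' @param rois data.frame with columns lane, row0, col0, row1, col1,
#'   concentration (0-based, half-open).
#' @param borderWidth background frame width for \code{\link{bandVolume}}.
#' @return a \linkS4class{DilutionFit}.
#' @export
quantifyGel <- function(image, rois, borderWidth = 3) {
  need <- c("row0", "col0", "row1", "col1", "concentration")
  if (!all(need %in% names(rois)))
    stop("'rois' must have columns row0, col0, row1, col1, concentration")
  vols <- vapply(seq_len(nrow(rois)), function(i)
    bandVolume(image, c(rois$row0[i], rois$col0[i], rois$row1[i], rois$col1[i]),
               borderWidth = borderWidth), 0)
  dilutionRegression(vols, rois$concentration)
}

#' Rank three alternating shots by R-squared
#'
#' Rank 1 is the largest R^2, rank 3 the smallest. Ties are broken by
#' acquisition order — the earlier shot takes the better rank (UV exposure
#' only fades the signal, so an equal later shot earned it against a
#' handicap) — and flagged.
#'
#' @param shotR2 three finite R^2 values in [0, 1], in acquisition order.
#' @return list with \code{ranks} (permutation of 1:3) and \code{tie}
#'   (logical).
#' @examples
#' rankExperiment(c(0.9962, 0.9866, 0.9947))$ranks   # 1 3 2
#' @export
rankExperiment <- function(shotR2) {
  shotR2 <- as.numeric(shotR2)
  if (length(shotR2) != 3L || !all(is.finite(shotR2)))
    stop("'shotR2' must be three finite values")
  if (any(shotR2 < 0 | shotR2 > 1)) stop("R^2 values must lie in [0, 1]")
  ranks <- rank(-shotR2, ties.method = "first")
  list(ranks = as.integer(ranks), tie = anyDuplicated(shotR2) > 0L)
}

#' Compare alternating-shot experiments between two cameras
#'
#' Each experiment photographs one gel three times in camera order A, B, A,
#' so UV-induced fading hits both cameras' comparison symmetrically. Per
#' experiment this reports the R^2 ranks of the three shots, the mean R^2 of
#' the two flanking (camera A) shots against the center (camera B) shot, and
#' the ratio of the flank-mean regression slope to the center slope after
#' optional per-shot exposure normalization. Across experiments a per-camera
#' R^2 summary is aggregated.
#'
#' @param experiments list of experiments; each is a list with
#'   \code{cameras}: the three camera ids in acquisition order (pattern
#'   A, B, A), and \code{fits}: three \linkS4class{DilutionFit} objects in
#'   the same order. An optional \code{exposureNorm} gives three per-shot
#'   normalization factors the slopes are divided by before comparison
#'   (default 1).
#' @return list with \code{perExperiment} (data.frame: experiment, flank and
#'   center cameras and R^2, slope ratio, ranks, tie flag) and
#'   \code{perCamera} (data.frame: camera, meanR2, shots).
#' @export
compareExperiments <- function(experiments) {
  if (!length(experiments)) stop("no experiments supplied")
  rows <- list(); camR2 <- list()
  for (i in seq_along(experiments)) {
    ex <- experiments[[i]]
    cams <- ex$cameras
    fits <- ex$fits
    if (length(cams) != 3L || cams[1] != cams[3] || cams[1] == cams[2])
      stop("experiment ", i, ": shots must follow the alternating A, B, A order")
    if (length(fits) != 3L || !all(vapply(fits, is, TRUE, "DilutionFit")))
      stop("experiment ", i, ": 'fits' must be three DilutionFit objects")
    en <- ex$exposureNorm %||% c(1, 1, 1)
    r2 <- vapply(fits, rSquared, 0)
    sl <- vapply(fits, function(f) f@slope, 0) / en
    rk <- rankExperiment(r2)
    rows[[i]] <- data.frame(
      experiment = i,
      flankCamera = cams[1], centerCamera = cams[2],
      flankMeanR2 = mean(r2[c(1, 3)]), centerR2 = r2[2],
      flankMeanSlope = mean(sl[c(1, 3)]), centerSlope = sl[2],
      slopeRatio = mean(sl[c(1, 3)]) / sl[2],
      rank1 = rk$ranks[1], rank2 = rk$ranks[2], rank3 = rk$ranks[3],
      tie = rk$tie
    )
    for (k in 1:3)
      camR2[[length(camR2) + 1L]] <- data.frame(camera = cams[k], r2 = r2[k])
  }
  perExperiment <- do.call(rbind, rows)
  allR2 <- do.call(rbind, camR2)
  perCamera <- do.call(rbind, lapply(split(allR2, allR2$camera), function(d)
    data.frame(camera = d$camera[1], meanR2 = mean(d$r2), shots = nrow(d))))
  rownames(perCamera) <- NULL
  list(perExperiment = perExperiment, perCamera = perCamera)
}
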