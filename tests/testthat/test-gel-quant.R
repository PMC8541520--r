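test_that("the identity homography reproduces the image", {
  img <- withSeedFixture(1, matrix(runif(40 * 60, 0, 255), 40, 60))
  quad <- rbind(c(0, 0), c(59, 0), c(59, 39), c(0, 39))
  out <- rectifyImage(img, quad, width = 60, height = 40)
  expect_lt(max(abs(out - img)), 1e-6)
})

test_that("the 4-point homography matches a null-space DLT oracle", {
  src <- rbind(c(3, 2), c(95, 6), c(90, 70), c(5, 66))
  dst <- rbind(c(0, 0), c(79, 0), c(79, 59), c(0, 59))
  H <- solveHomography(src, dst)
  Ho <- dltHomography(src, dst)
  expect_lt(max(abs(H - Ho)), 1e-9)
  ## corners map exactly
  mapped <- cbind(src, 1) %*% t(H)
  expect_equal(mapped[, 1:2] / mapped[, 3], dst, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(solveHomography(rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 1)), dst),
               "degenerate")
  expect_error(rectifyImage(matrix(0, 5, 5),
                            rbind(c(0, 0), c(4, 0), c(2, 2), c(0, 4)), 5, 5),
               "non-convex|degenerate")
})

test_that("warping onto a quad and rectifying back round-trips the gel", {
  g <- simulateGelImage(GelScene(noiseSigma = 0), seed = 1)
  quad <- rbind(c(12, 8), c(370, 16), c(362, 132), c(6, 124))
  gw <- simulateGelImage(GelScene(noiseSigma = 0, corners = quad), seed = 1)
  rec <- rectifyImage(gw$image, gw$corners, width = 360, height = 120)
  interior <- list(10:110, 10:350)
  expect_lt(mean(abs(rec[interior[[1]], interior[[2]]] -
                       g$image[interior[[1]], interior[[2]]])), 2)
  ## band volumes survive the round trip within 2%
  v0 <- quantifyGel(g$image, g$rois)
  v1 <- quantifyGel(rec, gw$rois)
  expect_lt(max(abs(bandVolumes(v1) / bandVolumes(v0) - 1)), 0.02)
})

test_that("band volume integrates background-subtracted intensity", {
  expect_equal(bandVolume(matrix(40, 60, 60), c(10, 10, 30, 30)), 0)
  ## single Gaussian band, zero background: analytic volume 2 pi A sigma^2
  rows <- 0:59; cols <- 0:59
  band <- 100 * outer(exp(-(rows - 30)^2 / 18), exp(-(cols - 30)^2 / 18))
  v <- bandVolume(band, c(10, 10, 51, 51))
  expect_lt(abs(v / (2 * pi * 100 * 9) - 1), 0.01)
  expect_error(bandVolume(band, c(-1, 0, 10, 10)), "bounds")
  expect_error(bandVolume(band, c(10, 10, 30, 30), borderWidth = 0), ">= 1")
})

test_that("band volume is additive over ROI partitions at fixed background", {
  img <- withSeedFixture(5, matrix(runif(50 * 50, 30, 80), 50, 50))
  whole <- bandVolume(img, c(10, 10, 40, 40), background = 30)
  parts <- bandVolume(img, c(10, 10, 25, 40), background = 30) +
    bandVolume(img, c(25, 10, 40, 40), background = 30)
  expect_equal(whole, parts, tolerance = 1e-9)
})

test_that("noise-free dilution gels quantify proportionally", {
  g <- simulateGelImage(GelScene(noiseSigma = 0), seed = 1)
  fit <- quantifyGel(g$image, g$rois)
  conc <- c(1, 1/2, 1/5, 1/10, 1/20)
  ratios <- bandVolumes(fit) / bandVolumes(fit)[1]
  expect_lt(max(abs(ratios / conc - 1)), 0.01)
  expect_gte(rSquared(fit), 0.999)
})

test_that("dilution regression matches the closed-form normal equations", {
  conc <- c(1, 0.5, 0.2, 0.1, 0.05)
  vols <- c(5, 4, 3, 2, 1)
  fit <- dilutionRegression(vols, conc)
  n <- length(conc)
  bOracle <- (n * sum(conc * vols) - sum(conc) * sum(vols)) /
    (n * sum(conc^2) - sum(conc)^2)
  aOracle <- mean(vols) - bOracle * mean(conc)
  r2Oracle <- 1 - sum((vols - aOracle - bOracle * conc)^2) /
    sum((vols - mean(vols))^2)
  expect_equal(fit@slope, bOracle, tolerance = 1e-12)
  expect_equal(fit@intercept, aOracle, tolerance = 1e-12)
  expect_equal(rSquared(fit), r2Oracle, tolerance = 1e-12)
  expect_equal(snr(fit), r2Oracle / (1 - r2Oracle), tolerance = 1e-12)
})

test_that("degenerate dilution regressions are flagged, not errors", {
  conc <- c(1, 0.5, 0.2, 0.1, 0.05)
  exact <- dilutionRegression(1000 * conc, conc)
  expect_equal(exact@slope, 1000, tolerance = 1e-9)
  expect_equal(exact@intercept, 0, tolerance = 1e-6)
  expect_equal(rSquared(exact), 1)
  expect_true(is.infinite(snr(exact)) && exact@degenerate)
  flat <- dilutionRegression(rep(7, 5), conc)
  expect_true(flat@degenerate && is.na(rSquared(flat)))
  expect_error(dilutionRegression(1:2, conc[1:2]), "3 points")
  expect_error(dilutionRegression(1:4, c(1, 1, 2, 3)), "distinct")
})

test_that("SNR and R-squared are exact inverses and monotone", {
  r2 <- seq(0, 0.999, length.out = 1000)
  s <- snrFromR2(r2)
  expect_lt(max(abs(r2FromSNR(s) - r2)), 1e-12)
  expect_true(all(diff(s) > 0))
  expect_equal(snrFromR2(0.5), 1)
  expect_equal(snrFromR2(1), Inf)
  expect_equal(r2FromSNR(Inf), 1)
  expect_error(snrFromR2(1.2), "\\[0, 1\\]")
})

test_that("shot ranking reproduces the recorded worked examples", {
  ex <- recordedRankExperiments()
  for (e in unique(ex$experiment)) {
    sub <- ex[ex$experiment == e, ]
    rk <- rankExperiment(sub$r2)
    expect_equal(rk$ranks, sub$recordedRank,
                 label = sprintf("experiment %d ranks", e))
    expect_false(rk$tie)
  }
  tie <- rankExperiment(c(0.9, 0.9, 0.8))
  expect_equal(tie$ranks, c(1L, 2L, 3L))
  expect_true(tie$tie)
  expect_error(rankExperiment(c(0.9, NA, 0.8)), "finite")
})

test_that("alternating-shot comparison separates flank and center cameras", {
  conc <- c(1, 0.5, 0.2, 0.1, 0.05)
  identicalFit <- dilutionRegression(1000 * conc + c(1, -2, 3, -1, 0.5), conc)
  cmp <- compareExperiments(list(list(cameras = c("A", "B", "A"),
                                      fits = list(identicalFit, identicalFit,
                                                  identicalFit))))
  expect_equal(cmp$perExperiment$flankMeanR2, cmp$perExperiment$centerR2)
  expect_equal(cmp$perExperiment$slopeRatio, 1)
  ## recorded first experiment: flanks beat the center shot
  ex1 <- recordedRankExperiments()
  r2 <- ex1$r2[ex1$experiment == 1]
  expect_equal(mean(r2[c(1, 3)]), 0.99545)
  expect_lt(r2[2], mean(r2[c(1, 3)]))
  expect_error(compareExperiments(list(list(cameras = c("A", "B", "C"),
                                            fits = list(identicalFit,
                                                        identicalFit,
                                                        identicalFit)))),
               "alternating")
})

test_that("a noisier flank camera loses the center comparison on average", {
  wins <- 0L
  for (s in 1:20) {
    shot <- function(noise, k) {
      g <- simulateGelImage(GelScene(noiseSigma = noise),
                            seed = s * 100 + k)
      quantifyGel(g$image, g$rois)
    }
    fits <- list(shot(6, 1), shot(1, 2), shot(6, 3))
    cmp <- compareExperiments(list(list(cameras = c("noisy", "clean", "noisy"),
                                        fits = fits)))
    wins <- wins + (cmp$perExperiment$centerR2 > cmp$perExperiment$flankMeanR2)
  }
  expect_gte(wins, 15L)
})

test_that("more simulator noise never raises the median dilution R-squared", {
  medR2 <- vapply(c(1, 4, 10), function(ns) {
    r2 <- vapply(1:20, function(s) {
      g <- simulateGelImage(GelScene(noiseSigma = ns), seed = s)
      rSquared(quantifyGel(g$image, g$rois))
    }, 0)
    median(r2)
  }, 0)
  expect_true(all(diff(medR2) <= 0))
})

test_that("automatic band finding locates the simulated lanes", {
  g <- simulateGelImage(GelScene(noiseSigma = 1), seed = 2)
  centers <- findBands(g$image)
  truth <- (seq_len(5) - 0.5) / 5 * 360 - 0.5
  expect_length(centers, 5L)
  expect_lt(max(abs(sort(centers) - truth)), 3)
})
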