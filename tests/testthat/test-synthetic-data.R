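field <- IlluminationField()

test_that("a linear camera images scale proportionally with duty cycle", {
  cam <- CameraModel("lin", gain = 200, gamma = 1, offset = 0, noiseSigma = 0)
  i100 <- simulateGradientImage(cam, field, 100, dim = c(8, 64), seed = 1)
  i50 <- simulateGradientImage(cam, field, 50, dim = c(8, 64), seed = 1)
  expect_equal(i50, 0.5 * i100, tolerance = 1e-12)
})

test_that("over-range signal clips exactly at saturation", {
  cam <- CameraModel("hot", gain = 600, gamma = 1, noiseSigma = 0)
  img <- simulateGradientImage(cam, field, 100, dim = c(4, 64), seed = 1)
  expect_true(any(img == 255))
  expect_lte(max(img), 255)
  ## the clipped columns are exactly at saturation, not merely near it
  raw <- 600 * fieldRadiance(field, (0:63) / 63, 100)
  expect_true(all(img[, raw > 255] == 255))
})

test_that("images are bit-identical under one seed and differ across seeds", {
  cam <- CameraModel("noisy", gain = 200, gamma = 1, noiseSigma = 2)
  a <- simulateGradientImage(cam, field, 80, dim = c(16, 64), seed = 11)
  b <- simulateGradientImage(cam, field, 80, dim = c(16, 64), seed = 11)
  c <- simulateGradientImage(cam, field, 80, dim = c(16, 64), seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("simulation leaves the session RNG stream untouched", {
  cam <- CameraModel("noisy", gain = 200, gamma = 1, noiseSigma = 2)
  set.seed(99); before <- .Random.seed
  invisible(simulateGradientImage(cam, field, 80, dim = c(8, 32), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("a PWM series is keyed by level and proportional when linear", {
  cam <- CameraModel("lin", gain = 200, gamma = 1, noiseSigma = 0)
  imgs <- simulatePWMSeries(cam, field, levels = c(100, 80, 60, 40, 20),
                            dim = c(8, 64), seed = 1)
  expect_named(imgs, c("100", "80", "60", "40", "20"))
  expect_equal(colMeans(imgs[["40"]]), 0.4 * colMeans(imgs[["100"]]),
               tolerance = 1e-12)
  only100 <- simulatePWMSeries(cam, field, levels = 100, dim = c(4, 32), seed = 1)
  expect_length(only100, 1L)
})

test_that("invalid simulator inputs are rejected", {
  cam <- CameraModel("lin", gain = 200, gamma = 1)
  expect_error(simulateGradientImage(cam, field, 120, dim = c(4, 32), seed = 1),
               "pwm")
  expect_error(simulateGradientImage(cam, field, 50, dim = c(0, 32), seed = 1),
               "positive")
  expect_error(simulatePWMSeries(cam, field, levels = c(80, 60), seed = 1),
               "reference")
  expect_error(simulatePWMSeries(cam, field, levels = c(100, 80, 80), seed = 1),
               "distinct")
  expect_error(CameraModel("bad", gain = -1), "gain")
  expect_error(IlluminationField(c(0.1, -2)), "non-negative")
})

test_that("brightness is monotone in duty for unclipped pixels", {
  cam <- CameraModel("g", gain = 220, gamma = 1.4, noiseSigma = 0)
  levels <- c(20, 40, 60, 80, 100)
  imgs <- lapply(levels, function(w)
    simulateGradientImage(cam, field, w, dim = c(4, 64), seed = 1))
  for (k in seq_along(levels)[-1]) {
    unclipped <- imgs[[k]] < 255
    expect_true(all(imgs[[k]][unclipped] >= imgs[[k - 1]][unclipped]))
  }
})

test_that("gel ground-truth volumes are exactly proportional to concentration", {
  g <- simulateGelImage(GelScene(noiseSigma = 0), seed = 1)
  expect_equal(g$volumes / g$volumes[1], c(1, 1/2, 1/5, 1/10, 1/20),
               tolerance = 1e-12)
  ## analytic single-band volume: 2 pi A sigma_r sigma_c
  sc <- GelScene(concentrations = 1, bandPeak = 90, bandSigmaRow = 4,
                 bandSigmaCol = 5, noiseSigma = 0)
  expect_equal(simulateGelImage(sc, seed = 1)$volumes,
               2 * pi * 90 * 4 * 5, tolerance = 1e-12)
})

test_that("bands that would overlap lane boundaries are rejected", {
  expect_error(simulateGelImage(GelScene(bandSigmaCol = 40), seed = 1),
               "lane boundaries")
  expect_error(simulateGelImage(GelScene(dim = c(30L, 360L)), seed = 1),
               "edge")
})

test_that("gel images are reproducible under a fixed seed", {
  sc <- GelScene(noiseSigma = 3)
  expect_identical(simulateGelImage(sc, seed = 4)$image,
                   simulateGelImage(sc, seed = 4)$image)
  expect_false(identical(simulateGelImage(sc, seed = 4)$image,
                         simulateGelImage(sc, seed = 5)$image))
})

test_that("image files round-trip through PNG and TIFF in counts", {
  img <- matrix(round(seq(0, 255, length.out = 96)), 8, 12)
  p8 <- withr::local_tempfile(fileext = ".png")
  writeImageGray(img, p8, bitDepth = 8)
  expect_equal(unclass(readImageGray(p8))[seq_along(img)], c(img),
               tolerance = 1e-9, ignore_attr = TRUE)
  p16 <- withr::local_tempfile(fileext = ".tif")
  writeImageGray(img * 200, p16, bitDepth = 16)
  back <- readImageGray(p16)
  expect_lt(max(abs(back - img * 200)), 0.51)  # 16-bit quantization step
})
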