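test_that("profile extraction normalizes positions and averages rows", {
  const <- matrix(7, 5, 40)
  p <- extractProfile(const)
  expect_equal(intensities(p), rep(7, 40))
  expect_equal(range(positions(p)), c(0, 1))

  ## identity gradient: column c holds value c
  grad <- matrix(rep(0:255, each = 3), nrow = 3)
  p <- extractProfile(grad)
  expect_equal(intensities(p), 0:255, ignore_attr = TRUE)
  expect_equal(positions(p), (0:255) / 255)
  ## un-normalizing recovers the original column indices
  expect_equal(positions(p) * (ncol(grad) - 1), 0:255)
})

test_that("profile values equal an independent per-column mean", {
  img <- withSeedFixture(42, matrix(runif(30 * 50, 0, 255), 30, 50))
  p <- extractProfile(img)
  oracle <- vapply(seq_len(ncol(img)), function(c) {
    s <- 0
    for (r in seq_len(nrow(img))) s <- s + img[r, c]
    s / nrow(img)
  }, 0)
  expect_equal(intensities(p), oracle, tolerance = 1e-12)
  ## rows axis is the transpose
  expect_equal(intensities(extractProfile(img, axis = "rows")),
               unname(rowMeans(img)), tolerance = 1e-12)
})

test_that("channel handling: green default on RGB, error on grayscale", {
  rgb <- array(0, dim = c(4, 16, 3))
  rgb[, , 2] <- matrix(rep(seq(0, 150, length.out = 16), each = 4), 4)
  rgb[, , 1] <- 42
  p <- extractProfile(rgb)
  expect_equal(intensities(p), seq(0, 150, length.out = 16))
  expect_equal(intensities(extractProfile(rgb, channel = "red")), rep(42, 16))
  expect_error(extractProfile(matrix(1, 4, 8), channel = "green"), "grayscale")
  expect_error(extractProfile(matrix(numeric(0), 0, 0)), "empty")
})

test_that("saturation bookkeeping warns above 1% saturated pixels", {
  img <- matrix(100, 10, 100); img[, 1:3] <- 255
  expect_warning(p <- extractProfile(img, saturation = 255), "saturated")
  expect_equal(p@meta$saturationFraction, 0.03)
  expect_silent(extractProfile(matrix(100, 10, 100), saturation = 255))
})

test_that("polynomial fits recover exact polynomials", {
  t <- seq(0, 1, length.out = 41)
  f1 <- fitPolynomial(IntensityProfile(t, 2 + 3 * t), 1)
  expect_equal(coef(f1), c(2, 3), tolerance = 1e-10)
  expect_lt(fitError(f1), 1e-10)

  y3 <- 1 + t - 2 * t^2 + 0.5 * t^3
  f3 <- fitPolynomial(IntensityProfile(t, y3), 3)
  expect_equal(coef(f3), c(1, 1, -2, 0.5), tolerance = 1e-8)
  expect_lt(fitError(f3), 1e-12)
  expect_equal(coef(f3, highestFirst = TRUE), rev(coef(f3)))
})

test_that("noisy fits agree with the normal-equations oracle", {
  t <- seq(0, 1, length.out = 101)
  y <- withSeedFixture(7, 5 + 40 * t - 25 * t^2 + 12 * t^3 + rnorm(101, 0, 2))
  f <- fitPolynomial(IntensityProfile(t, y), 3)
  expect_equal(coef(f), normalEqCoeffs(t, y, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fitError(f), oraclePopVar(y - powerSumPolyval(coef(f), t)),
               tolerance = 1e-12)
})

test_that("underdetermined fits are rejected", {
  p <- IntensityProfile(c(0, 0.5, 1), c(1, 2, 3))
  expect_error(fitPolynomial(p, 3), "underdetermined")
  expect_error(fitPolynomial(p, 0), ">= 1")
})

test_that("fit evaluation matches direct polynomial evaluation", {
  f <- fitPolynomial(IntensityProfile(c(0, 0.5, 1), c(5, 5, 5)), 1)
  expect_equal(evaluateFit(f, c(0, 0.3, 1)), rep(5, 3))
  lin <- fitPolynomial(IntensityProfile(seq(0, 1, 0.25), seq(0, 1, 0.25)), 1)
  expect_equal(evaluateFit(lin, 0.25), 0.25, tolerance = 1e-12)
  cub <- fitPolynomial(IntensityProfile(seq(0, 1, length.out = 25),
    powerSumPolyval(c(2, -1, 4, -2), seq(0, 1, length.out = 25))), 3)
  tq <- withSeedFixture(3, runif(100))
  expect_equal(evaluateFit(cub, tq), powerSumPolyval(coef(cub), tq),
               tolerance = 1e-12)
  expect_warning(evaluateFit(cub, 1.2), "extrapolation")
})

test_that("the residual-variance metric behaves as a population variance", {
  t <- seq(0, 1, length.out = 40)
  y <- 10 + 5 * t
  f <- fitPolynomial(IntensityProfile(t, y), 1)
  expect_equal(residualError(IntensityProfile(t, y), f), 0)
  ## alternating +/- 1 residuals have variance exactly 1
  expect_equal(residualError(IntensityProfile(t, y + rep(c(1, -1), 20)), f), 1)
  ## a constant offset is invisible to the metric (documented blind spot)
  expect_equal(residualError(IntensityProfile(t, y + 4), f), 0)
  f2 <- fitPolynomial(IntensityProfile(seq(0, 1, length.out = 10), 1:10), 1)
  expect_error(residualError(IntensityProfile(t, y), f2), "same t grid")
})

test_that("OLS optimality and order nesting hold on seeded profiles", {
  t <- seq(0, 1, length.out = 80)
  for (s in 1:5) {
    y <- withSeedFixture(s, 20 + 150 * t - 60 * t^2 + rnorm(80, 0, 3))
    prof <- IntensityProfile(t, y)
    f <- fitPolynomial(prof, 3)
    rss <- sum((y - fitted(f))^2)
    perturbed <- withSeedFixture(s + 100, replicate(25, {
      cp <- coef(f) + rnorm(4, 0, 0.05)
      sum((y - powerSumPolyval(cp, t))^2)
    }))
    expect_true(all(rss <= perturbed + 1e-9))
    errs <- vapply(1:6, function(n) fitError(fitPolynomial(prof, n)), 0)
    expect_true(all(diff(errs) <= 1e-9 * max(errs[1], 1)))
  }
})
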