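test_that("ROI noise estimates sample sigmas and their ratio", {
  set.seed(17)
  lnD <- matrix(rnorm(40 * 40, -0.3, 0.2), 40)
  lnT <- matrix(rnorm(40 * 40, -2.5, 0.04), 40)
  est <- roiNoise(lnD, lnT, c(1, 40, 1, 40))
  expect_equal(est@ratio, 5.0, tolerance = 0.06)
  expect_equal(est@source, "measured_roi")
  # identical noise fields give ratio 1
  est1 <- roiNoise(lnD, lnD, c(1, 30, 1, 30))
  expect_equal(est1@ratio, 1)
  # constant maps: sigmas 0, ratio NaN with warning
  cst <- matrix(1, 10, 10)
  expect_warning(est0 <- roiNoise(cst, cst, c(1, 10, 1, 10)), "undefined")
  expect_true(is.nan(est0@ratio))
  expect_equal(est0@sigmaLnD, 0)
  expect_error(roiNoise(lnD, lnT, c(30, 50, 1, 10)), "outside")
  expect_error(roiNoise(lnD, lnT, c(1, 4, 1, 4)), "25")
})

test_that("the shot-noise ratio evaluates its closed form", {
  expect_equal(shotNoiseRatio(1, 1, 0.365), 4.00, tolerance = 1e-3)
  expect_equal(shotNoiseRatio(0.05, 0.74, 0.365), 5.27, tolerance = 1e-3)
  # lower-noise limit at unit visibility and signals
  expect_equal(shotNoiseRatio(1, 1, 1), sqrt(3))
  expect_error(shotNoiseRatio(-0.1, 0.5), "domain")
  expect_error(shotNoiseRatio(0.5, 0.5, vRef = 1.2), "domain")
})

test_that("the shot-noise ratio agrees with Monte-Carlo propagation", {
  for (td in list(c(0.2, 0.74), c(1, 1))) {
    mc <- mcNoiseRatio(td[1], td[2], reps = 1e4, seed = 7)
    expect_equal(mc, shotNoiseRatio(td[1], td[2]), tolerance = 0.03)
  }
})

test_that("single-scan processing shows the predicted covariance deficit", {
  # estimating fringe mean and amplitude from the same stepping pass
  # couples them; the visibility variance drops by about V^2 relative to
  # the independence model, lowering the ratio at high visibility
  mc1 <- mcNoiseRatio(1, 1, reps = 2e4, seed = 19, split = FALSE)
  model <- shotNoiseRatio(1, 1)
  vr <- 0.365
  iv2 <- 2 / vr^2
  deficit <- sqrt((2 * iv2 - 2) / (2 * iv2 + 2))   # both scans at V = Vr
  expect_lt(mc1, model)
  expect_equal(mc1, model * deficit, tolerance = 0.03)
})

test_that("structural decomposition flags dark-field-dominant structure", {
  eq <- structuralDecomposition(5.2, 5.2)
  expect_equal(eq$quotient, 1)
  expect_false(eq$structuralDarkFieldDominant)
  hi <- structuralDecomposition(7.8, 5.2)
  expect_equal(hi$quotient, 1.5)
  expect_true(hi$structuralDarkFieldDominant)
  expect_false(structuralDecomposition(4, 5)$structuralDarkFieldDominant)
})

test_that("structurally flat phantom data show a quotient of one", {
  truth <- uniformTruth(muD = 1.5, density = 0.25)
  geom <- parallelGeometry()
  sp <- phantomSpec("high", fluxRef = 1e5, seed = 14)
  rad <- generatePhantomRadiographs(truth, geom, sp, noise = TRUE)
  cal <- buildCalibration(generateCalibrationStack(
    geometry = geom, spec = phantomSpec("high", seed = 1)))
  cor <- suppressMessages(correctBeamHardening(rad, cal))
  roi <- c(31, 70, 31, 70)
  est <- roiNoise(-log(darkField(cor)), -log(transmittance(cor)), roi)
  Tm <- median(transmittance(cor))
  Dm <- median(darkField(cor))
  dec <- structuralDecomposition(est@ratio,
                                 shotNoiseRatio(Tm, min(Dm, 1)))
  expect_equal(dec$quotient, 1, tolerance = 0.1)
})

test_that("normalized scatter divides slope by effective attenuation", {
  expect_equal(normalizedScatter(10.68, 25.42), 0.420, tolerance = 1e-3)
  expect_equal(normalizedScatter(14.20, 25.42), 0.559, tolerance = 1e-3)
  expect_equal(normalizedScatter(25.42, 25.42), 1)
  expect_error(normalizedScatter(10, -1), "> 0")
})

test_that("CNR ratio divides contrast ratio by noise ratio", {
  s <- cnrRatio(0.420, 7.8)
  expect_equal(s@cnrRatio, 0.054, tolerance = 1e-2)
  expect_equal(cnrRatio(0.559, 5.1)@cnrRatio, 0.110, tolerance = 1e-2)
  expect_equal(cnrRatio(0.5, 0.5)@cnrRatio, 1)
  expect_error(cnrRatio(0.4, 0), "> 0")
})

test_that("scatter and CNR ratios are scale-free in (slope, muEff)", {
  for (k in c(0.5, 2, 10)) {
    expect_equal(normalizedScatter(k * 12.86, k * 25.42),
                 normalizedScatter(12.86, 25.42))
  }
})

test_that("lung attenuation fraction follows its defining ratio", {
  dh <- matrix(c(0, 20, 40), 1, 3)
  lnT <- matrix(c(-1, -2, -40e-3 * 25.42), 1, 3)
  f <- suppressMessages(lungAttenuationFraction(dh, lnT, 25.42))
  expect_equal(f[1, 1], 0)
  expect_equal(f[1, 2], 0.254, tolerance = 1e-2)
  expect_equal(f[1, 3], 1)   # lung-only column
  # lnT = 0 is undefined
  f0 <- suppressMessages(lungAttenuationFraction(matrix(5), matrix(0),
                                                 25.42))
  expect_true(is.nan(f0[1, 1]))
})
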