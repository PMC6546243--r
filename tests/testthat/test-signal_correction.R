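test_that("visibility extraction recovers sinusoid modulation", {
  ph <- seq(0, 2 * pi, length.out = 9)[-9]
  expect_equal(visibilityFromStepping(2 + cos(ph), ph), 0.5)   # (3-1)/(3+1)
  expect_equal(visibilityFromStepping(rep(5, 8), ph), 0)
  # arbitrary phase offset
  expect_equal(visibilityFromStepping(10 + 3.65 * cos(ph + 1.1), ph),
               0.365)
  expect_error(visibilityFromStepping(c(1, 2), c(0, pi)), "at least 3")
  expect_error(visibilityFromStepping(-2 + cos(ph), ph), "invalid")
})

test_that("visibility extraction is unbiased under Poisson noise", {
  ph <- seq(0, 2 * pi, length.out = 9)[-9]
  set.seed(123)
  v <- replicate(100, {
    counts <- rpois(8, 12500 * (1 + 0.365 * cos(ph)))   # 1e5 counts total
    visibilityFromStepping(counts, ph)
  })
  expect_lt(abs(mean(v) - 0.365), 0.01)
  expect_lt(sd(v), 0.03)
})

mkRecords <- function(tNodes, nuNodes, heights = NULL, nCol = 4L) {
  # constant maps per height from scalar node values
  if (is.null(heights)) heights <- seq_along(tNodes) * 10
  list(heights = heights,
       tCal = lapply(tNodes, function(t) matrix(t, nCol, 3)),
       nuCal = lapply(nuNodes, function(v) matrix(v, nCol, 3)))
}

test_that("two-node calibration interpolates linearly through the nodes", {
  cal <- buildCalibration(mkRecords(c(0.5, 0.25), c(0.95, 0.90)))
  expect_equal(evalCalibration(cal, 0.5), 0.95)
  expect_equal(evalCalibration(cal, 0.25), 0.90)
  expect_equal(evalCalibration(cal, 0.375), 0.925)  # two nodes -> linear
  # constant extrapolation beyond the node range
  expect_equal(evalCalibration(cal, 0.9), 0.95)
  expect_equal(evalCalibration(cal, 0.01), 0.90)
})

test_that("unit calibration gives a unit interpolant", {
  cal <- buildCalibration(mkRecords(c(0.6, 0.3, 0.1), c(1, 1, 1)))
  expect_equal(evalCalibration(cal, c(0.1, 0.2, 0.45, 0.6)),
               rep(1, 4))
})

test_that("inconsistent or insufficient calibrations are rejected", {
  expect_error(buildCalibration(mkRecords(c(0.5), c(0.9))), "at least 2")
  expect_error(buildCalibration(mkRecords(c(0.25, 0.5), c(0.9, 0.95))),
               "decrease")
})

test_that("beam-hardening correction divides by nu_sec and keeps T", {
  cal <- buildCalibration(mkRecords(c(0.9, 0.2), c(0.9, 0.9), nCol = 2L))
  rad <- radiographSet(tMap = matrix(0.5, 2, 2),
                       nuMap = matrix(0.8, 2, 2),
                       flatIntensity = 1e4, flatVisibility = 0.365)
  cor <- correctBeamHardening(rad, cal)
  expect_equal(darkField(cor), matrix(0.8 / 0.9, 2, 2))
  expect_identical(transmittance(cor), transmittance(rad))
  # nu equal to nu_sec corrects to D = 1 everywhere
  rad1 <- radiographSet(matrix(0.5, 2, 2), matrix(0.9, 2, 2), 1e4, 0.365)
  expect_equal(darkField(correctBeamHardening(rad1, cal)),
               matrix(1, 2, 2))
  # width mismatch
  rad3 <- radiographSet(matrix(0.5, 3, 2), matrix(0.8, 3, 2), 1e4, 0.365)
  expect_error(correctBeamHardening(rad3, cal), "width")
})

test_that("correction then un-correction restores nu", {
  sp <- phantomSpec("mid", seed = 8)
  gen <- generatePhantomCT(sp)
  geom <- tinyGeometry()
  rad <- generatePhantomRadiographs(gen$truth, geom, sp, noise = TRUE)
  cal <- buildCalibration(generateCalibrationStack(geometry = geom,
                                                   spec = sp))
  cor <- suppressMessages(correctBeamHardening(rad, cal))
  nuSec <- visibilityReduction(cor) / darkField(cor)
  expect_equal(darkField(cor) * nuSec, visibilityReduction(rad),
               tolerance = 1e-14)
})

test_that("phantom secondary visibility loss is ~10% of log transmittance", {
  sp <- phantomSpec("high", bhFraction = 0.10, seed = 12)
  gen <- generatePhantomCT(sp)
  geom <- tinyGeometry()
  rad <- generatePhantomRadiographs(gen$truth, geom, sp)
  cal <- buildCalibration(generateCalibrationStack(geometry = geom,
                                                   spec = sp))
  cor <- suppressMessages(correctBeamHardening(rad, cal))
  dl <- mapValues(projectTruth(gen$truth, geom)$dLung)
  idx <- regressionMask(dl)
  nuSec <- visibilityReduction(cor) / darkField(cor)
  frac <- (-log(nuSec[idx])) / (-log(transmittance(cor)[idx]))
  expect_equal(median(frac), 0.10, tolerance = 0.05)
  expect_lt(abs(median(frac) - 0.10), 0.005)
})

test_that("the Compton offset follows the log intensity-ratio form", {
  expect_equal(comptonDelta(comptonModel(0.07, 0.07)), 0)
  expect_equal(comptonDelta(comptonModel(0.10, 0.05)),
               log(1.10 / 1.05), tolerance = 1e-12)
  expect_equal(comptonDelta(comptonModel(0.10, 0.05)), 0.04652,
               tolerance = 1e-4)
  # small ratios: Delta approaches the plain difference of the ratios
  d <- comptonDelta(comptonModel(0.02, 0.01))
  expect_equal(d, 0.00985, tolerance = 1e-3)
  expect_lt(abs(d - 0.01) / 0.01, 0.02)
  expect_error(comptonModel(-0.1, 0.05), ">= 0")
})
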