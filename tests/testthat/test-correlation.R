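test_that("the border-exclusion mask drops thin and empty lung pixels", {
  d <- matrix(c(0, 2, 2.9, 3, 5, 100), 2, 3)
  m <- regressionMask(d)
  expect_identical(as.vector(m), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("the dark-field variance model evaluates Eq-level examples", {
  expect_equal(darklung:::darkFieldVariance(1, 1, 0.365, 1), 32.02,
               tolerance = 1e-3)
  # 1/I_r proportionality: doubling the flux halves the variance exactly
  expect_equal(darklung:::darkFieldVariance(0.7, 0.1, 0.365, 2e4),
               darklung:::darkFieldVariance(0.7, 0.1, 0.365, 1e4) / 2)
  # sigma(ln D) via sigma(D)/D
  sdLn <- sqrt(darklung:::darkFieldVariance(0.74, 0.05, 0.365, 1e4)) / 0.74
  expect_equal(sdLn, 0.242, tolerance = 2e-3)
})

test_that("noise weights are normalized and reject bad inputs", {
  rad <- radiographSet(tMap = matrix(c(0.1, 0.2, 0.4, 1), 2, 2),
                       nuMap = matrix(0.8, 2, 2),
                       flatIntensity = 1e4, flatVisibility = 0.365,
                       dMap = matrix(c(0.7, 0.8, 0.9, 1), 2, 2))
  w <- noiseWeights(rad)
  expect_equal(mean(w), 1)
  expect_true(all(w > 0))
  radU <- radiographSet(matrix(0.5, 2, 2), matrix(0.8, 2, 2), 1e4, 0.365)
  expect_error(noiseWeights(radU), "corrected")
})

test_that("weighted least squares matches closed forms and lm", {
  x <- matrix(c(1, 2, 3), 1, 3)
  y <- matrix(c(1.1, 1.9, 3.2), 1, 3)
  fit <- weightedLinearFit(x, y)
  expect_equal(fitSlope(fit) / 1000, 1.05, tolerance = 1e-12)
  expect_equal(fitIntercept(fit), -1 / 30, tolerance = 1e-12)
  expect_equal(fitRSquared(fit), 0.981, tolerance = 1e-3)
  # exact line with arbitrary positive weights
  xe <- matrix(seq(0, 10, length.out = 7), 1)
  ye <- 2 * xe + 1
  we <- matrix(runif(7) + 0.1, 1)
  fe <- weightedLinearFit(xe, ye, we)
  expect_equal(fitSlope(fe) / 1000, 2, tolerance = 1e-12)
  expect_equal(fitIntercept(fe), 1, tolerance = 1e-12)
  expect_equal(fitRSquared(fe), 1)
  # uniform weights equal the unweighted closed form
  set.seed(31)
  xr <- matrix(runif(50, 0, 100), 5)
  yr <- 0.004 * xr - 0.05 + matrix(rnorm(50, 0, 0.05), 5)
  f1 <- weightedLinearFit(xr, yr)
  ref <- lm(as.vector(yr) ~ as.vector(xr))
  expect_equal(fitSlope(f1) / 1000, unname(coef(ref)[2]),
               tolerance = 1e-12)
  expect_equal(fitIntercept(f1), unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(fitRSquared(f1), summary(ref)$r.squared, tolerance = 1e-12)
})

test_that("adding a constant to y moves only the intercept", {
  set.seed(5)
  x <- matrix(runif(40, 0, 50), 4)
  y <- 0.003 * x + matrix(rnorm(40, 0, 0.02), 4)
  w <- matrix(runif(40) + 0.5, 4)
  f0 <- weightedLinearFit(x, y, w)
  f1 <- weightedLinearFit(x, y + 0.25, w)
  expect_equal(fitSlope(f1), fitSlope(f0), tolerance = 1e-12)
  expect_equal(fitIntercept(f1), fitIntercept(f0) + 0.25,
               tolerance = 1e-12)
})

test_that("degenerate regressions raise errors", {
  expect_error(weightedLinearFit(matrix(1, 1, 5), matrix(1:5, 1, 5)),
               "singular")
  expect_error(weightedLinearFit(matrix(1, 1, 1), matrix(1, 1, 1)),
               "two included")
})

test_that("power-law fits recover exact power laws", {
  f <- powerLawFit(c(1, 2, 4), c(5, 2.5, 1.25))
  expect_equal(powerLawPrefactor(f), 5, tolerance = 1e-12)
  expect_equal(powerLawExponent(f), -1, tolerance = 1e-12)
  V <- c(0.5, 1, 2)
  f2 <- powerLawFit(V, 3 * V^-0.8)
  expect_equal(powerLawExponent(f2), -0.8, tolerance = 1e-12)
  expect_equal(powerLawPrefactor(f2), 3, tolerance = 1e-12)
  expect_error(powerLawFit(c(1, -2), c(1, 1)), "positive")
  expect_error(powerLawFit(1, 5), "at least two")
})

test_that("ventilation summaries report percent changes vs lowest pressure", {
  fits <- data.frame(
    animal = rep(c(1, 2), each = 6),
    pressure = rep(c(2, 11, 20), 4),
    xKind = rep(rep(c("d_lung", "d_h2o"), each = 3), 2),
    slope = c(4.11, 2.74, 2.38, 10.68, 11.11, 10.82,
              4.62, 3.48, 3.10, 12.86, 13.70, 14.20))
  vols <- data.frame(animal = rep(c(1, 2), each = 3),
                     pressure = rep(c(2, 11, 20), 2),
                     volume = c(0.76, 1.20, 1.37, 0.78, 1.06, 1.24))
  out <- ventilationSummary(fits, vols)
  get <- function(an, p, k)
    out$slopeChangePct[out$animal == an & out$pressure == p &
                       out$xKind == k]
  expect_equal(get(1, 20, "d_lung"), -42, tolerance = 0.005)
  expect_equal(get(2, 20, "d_lung"), -33, tolerance = 0.005)
  expect_equal(get(1, 11, "d_h2o"), 4, tolerance = 0.01)
  expect_equal(get(2, 20, "d_h2o"), 10, tolerance = 0.05)
  expect_equal(out$volumeChangePct[out$animal == 1 & out$pressure == 20][1],
               80, tolerance = 0.005)
  # equal slopes give zero change
  same <- ventilationSummary(data.frame(animal = 1, pressure = c(2, 20),
                                        xKind = "d_lung",
                                        slope = c(3, 3)))
  expect_equal(same$slopeChangePct, c(0, 0))
  expect_error(ventilationSummary(data.frame(animal = 1, pressure = 2,
                                             xKind = "d_lung", slope = 3)),
               "two pressure")
})
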