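test_that("phantom generation is deterministic for a given seed", {
  a <- generatePhantomCT(phantomSpec("mid", seed = 42))
  b <- generatePhantomCT(phantomSpec("mid", seed = 42))
  expect_identical(voxelData(a$ct), voxelData(b$ct))
  c <- generatePhantomCT(phantomSpec("mid", seed = 43))
  expect_false(identical(voxelData(a$ct), voxelData(c$ct)))
})

test_that("zero lung semi-axes give an empty lung", {
  gen <- generatePhantomCT(phantomSpec("high", lungScale = 0, seed = 1))
  thr <- segmentationThresholds("inspiration")
  inWindow <- voxelData(gen$ct) > thr@lLow & voxelData(gen$ct) < thr@lHigh
  expect_equal(sum(inWindow), 0)
  expect_equal(gen$truth@lungVolumeTrue, 0)
})

test_that("lung voxels stay inside the state's segmentation window", {
  gen <- generatePhantomCT(phantomSpec("high", lungMeanHU = -700, seed = 9))
  hu <- voxelData(gen$ct)[gen$truth@lungMask == 1]
  expect_true(all(hu > -922 & hu < -512))
  # truth density is consistent with the HU volume
  expect_equal(gen$truth@densityField,
               (voxelData(gen$ct) + 1000) / 1000)
})

test_that("ventilation states conserve lung mass (density ~ 1/volume)", {
  vols <- dens <- numeric(0)
  for (st in c("low", "mid", "high")) {
    gen <- generatePhantomCT(phantomSpec(st, seed = 4))
    m <- gen$truth@lungMask == 1
    vols <- c(vols, gen$truth@lungVolumeTrue)
    dens <- c(dens, mean(gen$truth@densityField[m]))
  }
  fit <- powerLawFit(vols, dens)
  expect_equal(powerLawExponent(fit), -1, tolerance = 0.02)
})

test_that("a bronchus is excluded from lung truth and segmentation", {
  with_br <- generatePhantomCT(phantomSpec("high", bronchus = TRUE,
                                           seed = 3))
  without <- generatePhantomCT(phantomSpec("high", seed = 3))
  expect_lt(with_br$truth@lungVolumeTrue, without$truth@lungVolumeTrue)
  seg <- segmentLung(with_br$ct, segmentationThresholds("inspiration"))
  # closing may re-bridge isolated notches at the airway wall, but the
  # segmentation deviates from the truth compartment by well under a
  # voxel shell and the airway core stays excluded
  mism <- mean(voxelData(seg) != with_br$truth@lungMask)
  expect_lt(mism, 0.005)
  dims <- dim(with_br$truth@lungMask)
  vox <- voxelSize(seg)
  org <- gridOrigin(seg)
  x <- org[1] + (seq_len(dims[1]) - 1) * vox[1]
  y <- org[2] + (seq_len(dims[2]) - 1) * vox[2]
  z <- org[3] + (seq_len(dims[3]) - 1) * vox[3]
  X <- array(x, dims)
  Y <- array(rep(y, each = dims[1]), dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dims)
  core <- (X - 55)^2 + Y^2 <= 4^2 & abs(Z) <= 20
  expect_equal(sum(voxelData(seg)[core]), 0)
})

test_that("noise-free radiographs follow the construction exactly", {
  # with bhFraction = 0 the measured visibility reduction equals the
  # corrected dark-field signal, so the construction can be checked on nu
  sp <- phantomSpec("high", deltaTrue = 0, bhFraction = 0, seed = 6)
  gen <- generatePhantomCT(sp)
  geom <- tinyGeometry()
  rad <- generatePhantomRadiographs(gen$truth, geom, sp)
  tr <- projectTruth(gen$truth, geom)
  # -ln D equals mu_d * d_lung (d_lung in m) at machine precision
  expect_equal(-log(visibilityReduction(rad)),
               sp@muDTrue * mapValues(tr$dLung) / 1000, tolerance = 1e-12)
  # -ln T equals muEffSim * d_h2o of the whole body
  expect_equal(-log(transmittance(rad)),
               sp@muEffSim * mapValues(tr$dH2O) / 1000, tolerance = 1e-12)
  # dMap is filled by correction, not construction
  expect_null(darkField(rad))
})

test_that("the Compton intercept appears where no lung is traversed", {
  sp <- phantomSpec("high", deltaTrue = -0.05, bhFraction = 0, seed = 6)
  gen <- generatePhantomCT(sp)
  geom <- tinyGeometry()
  rad <- generatePhantomRadiographs(gen$truth, geom, sp)
  dl <- mapValues(projectTruth(gen$truth, geom)$dLung)
  outside <- dl == 0
  expect_equal(unique(round(-log(visibilityReduction(rad))[outside], 12)),
               -0.05)
})

test_that("injected noise matches the stepping variance model", {
  truth <- uniformTruth(muD = 1.5, density = 0.25)
  geom <- parallelGeometry()   # replicate pixels at identical (T, D)
  sp <- phantomSpec("high", fluxRef = 1e4, seed = 21)
  rad0 <- generatePhantomRadiographs(truth, geom, sp, noise = FALSE)
  rad <- generatePhantomRadiographs(truth, geom, sp, noise = TRUE)
  T0 <- transmittance(rad0)[1, 1]
  D0 <- exp(-(-log(visibilityReduction(rad0)[1, 1]) -
              sp@bhFraction * (-log(T0))))
  expect_equal(sd(transmittance(rad0)), 0)
  D <- visibilityReduction(rad) / transmittance(rad)^sp@bhFraction
  predD <- darklung:::darkFieldVariance(D0, T0, sp@visibilityRef,
                                        sp@fluxRef)
  expect_equal(var(as.vector(D)), predD, tolerance = 0.05)
  predT <- T0^2 * (1 + 1 / T0) / sp@fluxRef
  expect_equal(var(as.vector(transmittance(rad))), predT, tolerance = 0.05)
})

test_that("noise with non-positive flux is rejected", {
  truth <- uniformTruth()
  sp <- phantomSpec("high", seed = 1)
  sp@fluxRef <- 0
  expect_error(generatePhantomRadiographs(truth, parallelGeometry(), sp,
                                          noise = TRUE), "flux")
})

test_that("calibration stacks follow Beer-Lambert and the bh relation", {
  sp <- phantomSpec("high", seed = 1)
  geom <- tinyGeometry(c(8L, 8L), 4)
  recs <- generateCalibrationStack(c(64, 96, 128), geom, sp)
  # T decreasing with height at every pixel
  expect_true(all(recs$tCal[[3]] < recs$tCal[[1]]))
  expect_true(all(recs$tCal[[2]] < recs$tCal[[1]]))
  # -ln nu = bh * -ln T
  for (k in 1:3)
    expect_equal(-log(recs$nuCal[[k]]),
                 sp@bhFraction * -log(recs$tCal[[k]]), tolerance = 1e-12)
  # no beam hardening: all nu identically 1
  sp0 <- phantomSpec("high", bhFraction = 0, seed = 1)
  recs0 <- generateCalibrationStack(c(64, 128), geom, sp0)
  expect_true(all(recs0$nuCal[[1]] == 1 & recs0$nuCal[[2]] == 1))
  expect_error(generateCalibrationStack(c(64), geom, sp), "at least 2")
  expect_error(generateCalibrationStack(c(64, 64), geom, sp),
               "increasing")
})

test_that("phantom specs with lungs outside the body are invalid", {
  sp <- phantomSpec("high", seed = 1)
  expect_error({sp@lungCenters[1, 2] <- 90; validObject(sp)},
               "strictly inside")
  expect_error(phantomSpec("high", lungMeanHU = -400), "window")
})
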