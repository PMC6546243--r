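test_that("HU to relative attenuation is the air/water linear rescale", {
  ct <- ctVolume(array(c(-1000, 0, -500, 250, -1024, 500), c(3, 2, 1)),
                 c(1, 1, 1))
  expect_message(rel <- huToRelativeAttenuation(ct), "clamping")
  expect_equal(voxelData(rel)[1:4], c(0, 1, 0.5, 1.25))
  expect_equal(voxelData(rel)[5], 0)   # below air floor: clamped, logged
})

test_that("HU below the air floor clamps with a message", {
  expect_message(ct <- ctVolume(array(-1100, c(2, 2, 2)), c(1, 1, 1)),
                 "clamping")
  expect_true(all(voxelData(ct) == -1024))
})

test_that("segmentation uses strict thresholds on both sides", {
  mk <- function(hu) ctVolume(array(hu, c(1, 1, 1)), c(1, 1, 1))
  insp <- segmentationThresholds("inspiration")
  expi <- segmentationThresholds("expiration")
  seg1 <- function(hu, thr)
    voxelData(segmentLung(mk(hu), thr, closing = FALSE))[1]
  expect_equal(seg1(-700, insp), 1)   # inside the 20/11 mbar window
  expect_equal(seg1(-400, expi), 0)   # -400 >= -410: excluded
  expect_equal(seg1(-410, expi), 0)   # boundary excluded (strict)
  expect_equal(seg1(-922, insp), 0)
  expect_equal(seg1(-921, insp), 1)
})

test_that("threshold presets and explicit windows validate", {
  thr <- segmentationThresholds("inspiration")
  expect_equal(c(thr@lLow, thr@lHigh), c(-922, -512))
  thr <- segmentationThresholds("expiration")
  expect_equal(c(thr@lLow, thr@lHigh), c(-870, -410))
  expect_error(segmentationThresholds(lLow = -400, lHigh = -870),
               "smaller")
})

test_that("binary closing fills a unit hole and is idempotent", {
  hu <- array(-700, c(7, 7, 7))
  hu[4, 4, 4] <- 0   # isolated dense voxel fully surrounded by lung
  ct <- ctVolume(hu, c(1, 1, 1))
  thr <- segmentationThresholds("inspiration")
  seg <- segmentLung(ct, thr)
  expect_equal(voxelData(seg)[4, 4, 4], 1)
  # closing is idempotent on its own output
  closed <- darklung:::closing3d(voxelData(seg))
  expect_identical(closed, voxelData(seg))
  # without closing the hole stays
  raw <- segmentLung(ct, thr, closing = FALSE)
  expect_equal(voxelData(raw)[4, 4, 4], 0)
})

test_that("masking is the elementwise product with support equality", {
  d <- c(4, 4, 2)
  chk <- array(as.numeric((slice.index(array(0, d), 1) +
                           slice.index(array(0, d), 2) +
                           slice.index(array(0, d), 3)) %% 2), d)
  s <- new("BinaryVolume", s = chk, voxelSize = c(1, 1, 1),
           origin = c(0, 0, 0))
  rel <- new("AttenuationVolume", m = array(0.3, d),
             voxelSize = c(1, 1, 1), origin = c(0, 0, 0))
  m <- maskAttenuation(s, rel)
  expect_equal(voxelData(m), 0.3 * chk)
  expect_identical(voxelData(m) != 0, chk == 1)
  s0 <- new("BinaryVolume", s = array(0, d), voxelSize = c(1, 1, 1),
            origin = c(0, 0, 0))
  expect_true(all(voxelData(maskAttenuation(s0, rel)) == 0))
  bad <- new("AttenuationVolume", m = array(0.3, c(2, 2, 2)),
             voxelSize = c(1, 1, 1), origin = c(0, 0, 0))
  expect_error(maskAttenuation(s, bad), "same grid")
})

test_that("lung volume converts voxel counts to liters", {
  s <- new("BinaryVolume", s = array(1, c(100, 100, 100)),
           voxelSize = c(1, 1, 1), origin = c(0, 0, 0))
  expect_equal(lungVolume(s), 1.0)   # 1e6 voxels of 1 mm^3
  s0 <- new("BinaryVolume", s = array(0, c(4, 4, 4)),
            voxelSize = c(1, 1, 1), origin = c(0, 0, 0))
  expect_equal(lungVolume(s0), 0.0)
  s4 <- new("BinaryVolume",
            s = array(c(rep(1, 4), rep(0, 60)), c(4, 4, 4)),
            voxelSize = c(0.5, 0.5, 1.0), origin = c(0, 0, 0))
  expect_equal(lungVolume(s4), 4 * 0.25 / 1e6)   # 1 mm^3 total
})

test_that("segmentation of the phantom recovers the true lung volume", {
  gen <- generatePhantomCT(phantomSpec("mid", seed = 11))
  seg <- segmentLung(gen$ct, segmentationThresholds("inspiration"))
  expect_identical(voxelData(seg), gen$truth@lungMask)
  expect_equal(lungVolume(seg), gen$truth@lungVolumeTrue)
})
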