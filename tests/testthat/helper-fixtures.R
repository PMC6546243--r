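# Shared fixtures, built in code.

# reduced detector for unit tests; acceptance tests use defaultGeometry()
tinyGeometry <- function(shape = c(96L, 96L), pitch = 4.5) {
  defaultGeometry(detectorShape = as.integer(shape), pixelPitch = pitch)
}

# uniform sphere with partial-volume (supersampled) edge voxels, so that
# line integrals can be compared against the analytic chord 2 sqrt(r^2-b^2)
sphereVolume <- function(radius = 50, vox = 1, sub = 4L) {
  n <- as.integer(ceiling(2 * (radius + 3) / vox))
  org <- -(n - 1) / 2 * vox
  x <- org + (0:(n - 1)) * vox
  off <- (seq_len(sub) - (sub + 1) / 2) / sub * vox
  s <- array(0, c(n, n, n))
  for (ox in off) for (oy in off) for (oz in off) {
    X <- array(x + ox, c(n, n, n))
    Y <- array(rep(x + oy, each = n), c(n, n, n))
    Z <- array(rep(x + oz, each = n * n), c(n, n, n))
    s <- s + (X^2 + Y^2 + Z^2 <= radius^2)
  }
  new("AttenuationVolume", m = s / sub^3, voxelSize = rep(vox, 3),
      origin = rep(org, 3))
}

# single-pixel geometry whose ray runs in +y through (x0, ., z0),
# effectively parallel (source 50 m away)
pencilGeometry <- function(x0, z0 = 0, pitch = 1) {
  projectionGeometry(c(x0, -5e4, z0), c(x0, 200, z0),
                     cbind(c(1, 0, 0), c(0, 0, 1)), pitch, c(1L, 1L))
}

# slab of given thickness along z (value 1 inside), vox mm voxels
slabVolume <- function(thickness = 16, vox = 2, n = c(60L, 60L, 24L)) {
  s <- array(0, n)
  z0 <- n[3] / 2
  nz <- thickness / vox
  s[, , (z0 - nz / 2 + 1):(z0 + nz / 2)] <- 1
  new("BinaryVolume", s = s, voxelSize = rep(vox, 3),
      origin = -(n - 1) / 2 * vox)
}

# phantom truth with spatially constant fields and a near-parallel beam:
# every central detector pixel sees identical (T, D), giving replicate
# pixels for Monte-Carlo noise checks
uniformTruth <- function(muD = 2, density = 0.3, muEffSim = 25.4,
                         delta = 0, bh = 0.1) {
  n <- c(8L, 8L, 8L)
  ones <- array(1, n)
  new("PhantomTruth", muDField = muD * ones, densityField = density * ones,
      lungMask = ones, lungVolumeTrue = sum(ones) * 1e-3,
      deltaTrue = delta, bhFraction = bh, muEffSim = muEffSim,
      voxelSize = c(10, 10, 10), origin = -(n - 1) / 2 * 10)
}

parallelGeometry <- function(shape = c(100L, 100L), pitch = 0.5) {
  half <- (shape - 1) / 2 * pitch
  projectionGeometry(c(0, -1e6, 0), c(-half[1], 200, -half[2]),
                     cbind(c(1, 0, 0), c(0, 0, 1)), pitch,
                     as.integer(shape))
}
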