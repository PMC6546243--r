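# Lung segmentation, HU conversion, masking and lung volume.

#' Construct a CT volume
#'
#' @param hu 3-D array of Hounsfield units. Values below -1024 are clamped to
#'   -1024 with a message (reconstruction dialects differ in their air floor).
#' @param voxelSize numeric(3), voxel edge lengths in mm.
#' @param origin numeric(3), physical position of the first voxel center (mm).
#' @return a \linkS4class{CTVolume}.
#' @export
ctVolume <- function(hu, voxelSize, origin = c(0, 0, 0)) {
  hu <- as.array(hu)
  nlow <- sum(hu < -1024)
  if (nlow > 0) {
    message(sprintf("clamping %d voxels below -1024 HU", nlow))
    hu[hu < -1024] <- -1024
  }
  new("CTVolume", hu = hu, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' Segmentation threshold windows
#'
#' Either an explicit Hounsfield window or one of the two named presets:
#' \code{"inspiration"} (-922, -512), used for mid and high ventilation
#' pressures, and \code{"expiration"} (-870, -410), used for the low
#' pressure, where the partially collapsed lung is denser.
#'
#' @param preset "inspiration" or "expiration", or NULL when giving bounds.
#' @param lLow,lHigh explicit window bounds in HU (ignored when a preset is
#'   given).
#' @return a \linkS4class{SegmentationThresholds}.
#' @export
segmentationThresholds <- function(preset = NULL, lLow = NULL, lHigh = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("inspiration", "expiration"))
    b <- switch(preset, inspiration = c(-922, -512),
                expiration = c(-870, -410))
    return(new("SegmentationThresholds", lLow = b[1], lHigh = b[2]))
  }
  new("SegmentationThresholds", lLow = as.numeric(lLow),
      lHigh = as.numeric(lHigh))
}

# ventilation state -> threshold preset
stateToPreset <- function(state) {
  switch(state, low = "expiration", mid = "inspiration",
         high = "inspiration")
}

#' Convert Hounsfield units to water-relative attenuation
#'
#' Linear rescaling (HU + 1000) / 1000, anchored at air (-1000 HU -> 0) and
#' water (0 HU -> 1). The result is not yet masked to the lung.
#'
#' @param ct a \linkS4class{CTVolume}.
#' @return an \linkS4class{AttenuationVolume} on the same grid.
#' @export
huToRelativeAttenuation <- function(ct) {
  stopifnot(is(ct, "CTVolume"))
  m <- (ct@hu + 1000) / 1000
  nneg <- sum(m < 0)
  if (nneg > 0) {
    message(sprintf("clamping %d voxels below -1000 HU to zero attenuation",
                    nneg))
    m[m < 0] <- 0
  }
  new("AttenuationVolume", m = m, voxelSize = ct@voxelSize,
      origin = ct@origin)
}

# 3x3x3 binary dilation/erosion with zero edge padding, via array shifts.
shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

morph3d <- function(a, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(a)
  # erosion with 0-padding: border voxels see padded 0 neighbors
  acc <- if (op == "dilate") array(0, d) else array(1, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    s <- shift3d(a, dx, dy, dz)
    acc <- if (op == "dilate") pmax(acc, s) else pmin(acc, s)
  }
  acc
}

closing3d <- function(a) morph3d(morph3d(a, "dilate"), "erode")

#' Segment the lung by Hounsfield thresholding
#'
#' A voxel belongs to the lung iff lLow < HU < lHigh (strict on both sides);
#' small holes are then removed by binary closing with a full 3 x 3 x 3
#' structuring element (zero padding at the volume borders). Interiors of
#' larger airways fall outside the window and stay excluded.
#'
#' @param ct a \linkS4class{CTVolume}.
#' @param thresholds a \linkS4class{SegmentationThresholds}.
#' @param closing apply the 3 x 3 x 3 binary closing (default TRUE).
#' @return a \linkS4class{BinaryVolume}.
#' @export
segmentLung <- function(ct, thresholds, closing = TRUE) {
  stopifnot(is(ct, "CTVolume"), is(thresholds, "SegmentationThresholds"))
  s <- array(as.numeric(ct@hu > thresholds@lLow & ct@hu < thresholds@lHigh),
             dim(ct@hu))
  if (closing) s <- closing3d(s)
  new("BinaryVolume", s = s, voxelSize = ct@voxelSize, origin = ct@origin)
}

#' Mask an attenuation volume to the segmented lung
#'
#' Elementwise product of the binary segmentation and the relative
#' attenuation volume, isolating the part of the attenuation signal that
#' originates in the lung.
#'
#' @param s a \linkS4class{BinaryVolume}.
#' @param rel an \linkS4class{AttenuationVolume} on the same grid.
#' @return a masked \linkS4class{AttenuationVolume}.
#' @export
maskAttenuation <- function(s, rel) {
  stopifnot(is(s, "BinaryVolume"), is(rel, "AttenuationVolume"))
  if (!identical(dim(s@s), dim(rel@m)))
    stop("segmentation and attenuation volumes must share the same grid")
  new("AttenuationVolume", m = s@s * rel@m, voxelSize = rel@voxelSize,
      origin = rel@origin)
}

#' Segmented lung volume in liters
#'
#' Number of set voxels times the voxel volume.
#'
#' @param s a \linkS4class{BinaryVolume}.
#' @return volume in liters.
#' @export
lungVolume <- function(s) {
  stopifnot(is(s, "BinaryVolume"))
  sum(s@s) * prod(s@voxelSize) / 1e6
}
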