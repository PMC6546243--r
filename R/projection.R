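# Cone-beam forward projection of volumes into the radiograph frame.

#' Construct a cone-beam projection geometry
#'
#' All coordinates are in mm in a common geometry frame. Detector pixel
#' (0, 0) is centered at \code{detectorOrigin} and pixel (i, j) at
#' \code{detectorOrigin + i * pixelPitch * axis1 + j * pixelPitch * axis2}
#' (0-based indices). The rigid volume pose maps volume-frame coordinates
#' into the geometry frame.
#'
#' @param sourcePosition numeric(3), X-ray source position.
#' @param detectorOrigin numeric(3), center of detector pixel (0, 0).
#' @param detectorAxes 3 x 2 matrix whose columns are orthonormal in-plane
#'   unit vectors.
#' @param pixelPitch pixel spacing in mm.
#' @param detectorShape integer(2), pixel counts.
#' @param volumeRotation 3 x 3 rotation of the volume pose (default
#'   identity).
#' @param volumeTranslation numeric(3), translation of the volume pose
#'   (default zero).
#' @return a \linkS4class{ProjectionGeometry}.
#' @export
projectionGeometry <- function(sourcePosition, detectorOrigin, detectorAxes,
                               pixelPitch, detectorShape,
                               volumeRotation = diag(3),
                               volumeTranslation = c(0, 0, 0)) {
  new("ProjectionGeometry",
      sourcePosition = as.numeric(sourcePosition),
      detectorOrigin = as.numeric(detectorOrigin),
      detectorAxes = detectorAxes, pixelPitch = as.numeric(pixelPitch),
      detectorShape = as.integer(detectorShape),
      volumeRotation = volumeRotation,
      volumeTranslation = as.numeric(volumeTranslation))
}

#' Default phantom acquisition geometry
#'
#' A vertical cone beam matched to the digital thorax phantom: source 900 mm
#' in front of the volume center, detector 450 mm behind it (magnification
#' 1.5), with a detector large enough to cover the projected thorax.
#'
#' @param detectorShape integer(2) pixel counts (default 288 x 288).
#' @param pixelPitch pixel spacing in mm (default 1.5).
#' @return a \linkS4class{ProjectionGeometry}.
#' @export
defaultGeometry <- function(detectorShape = c(288L, 288L),
                            pixelPitch = 1.5) {
  half <- (as.integer(detectorShape) - 1L) / 2 * pixelPitch
  projectionGeometry(
    sourcePosition = c(0, -900, 0),
    detectorOrigin = c(-half[1], 450, -half[2]),
    detectorAxes = cbind(c(1, 0, 0), c(0, 0, 1)),
    pixelPitch = pixelPitch, detectorShape = detectorShape)
}

#' Trilinear interpolation of a volume at physical points
#'
#' Interpolates the voxel grid from the discrete to the continuous domain;
#' the field is zero outside the span of voxel centers.
#'
#' @param volume a \linkS4class{BinaryVolume} or
#'   \linkS4class{AttenuationVolume} (a \linkS4class{CTVolume} is also
#'   accepted).
#' @param points an n x 3 matrix (or length-3 vector) of volume-frame
#'   coordinates in mm.
#' @return numeric vector of interpolated values.
#' @export
interpolateContinuous <- function(volume, points) {
  a <- voxelData(volume)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  .trilinearCpp(as.numeric(a), dim(a), voxelSize(volume),
                gridOrigin(volume), as.matrix(points))
}

#' Cone-beam forward projection
#'
#' For every detector pixel, the line integral of the trilinearly
#' interpolated volume along the straight ray from the source through the
#' pixel center, computed by fixed-step ray marching with the midpoint rule.
#' Projecting a binary segmentation gives the projected lung thickness
#' d_lung; projecting a masked relative-attenuation volume gives the
#' water-equivalent height d_h2o. Both are in mm.
#'
#' @param volume a \linkS4class{BinaryVolume} or
#'   \linkS4class{AttenuationVolume}.
#' @param geometry a \linkS4class{ProjectionGeometry}.
#' @param stepFactor ray step as a fraction of the smallest voxel dimension
#'   (default 0.25; halve it to test convergence).
#' @return a \linkS4class{ProjectionMap} with kind "d_lung" for binary input
#'   and "d_h2o" for attenuation input.
#' @export
forwardProject <- function(volume, geometry, stepFactor = 0.25) {
  stopifnot(is(geometry, "ProjectionGeometry"))
  validObject(geometry)
  if (stepFactor <= 0) stop("stepFactor must be > 0")
  a <- voxelData(volume)
  if (any(!is.finite(a))) stop("volume must be finite")
  vals <- .forwardProjectCpp(
    as.numeric(a), dim(a), voxelSize(volume), gridOrigin(volume),
    geometry@volumeRotation, geometry@volumeTranslation,
    geometry@sourcePosition, geometry@detectorOrigin,
    geometry@detectorAxes, geometry@pixelPitch, geometry@detectorShape,
    stepFactor)
  kind <- if (is(volume, "BinaryVolume")) "d_lung" else "d_h2o"
  vals[vals < 0] <- 0
  new("ProjectionMap", values = vals, kind = kind,
      pixelPitch = geometry@pixelPitch)
}
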