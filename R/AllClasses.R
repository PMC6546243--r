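# S4 containers for the dark-field lung analysis. All physical lengths are in
# mm unless stated otherwise; attenuation and extinction coefficients are
# reported in 1/m.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Virtual parent for voxel grids
#'
#' Common geometry slots of the volumetric containers: voxel edge lengths
#' (mm, one per axis) and the physical position of the first voxel center
#' (mm, in the volume frame).
#'
#' @slot voxelSize numeric(3), voxel edge lengths in mm, all > 0.
#' @slot origin numeric(3), position of the first voxel center in mm.
#' @exportClass VoxelGrid
setClass("VoxelGrid", representation("VIRTUAL",
  voxelSize = "numeric", origin = "numeric"))

validVoxelGrid <- function(object) {
  msg <- character()
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values (mm)")
  if (length(msg)) msg else TRUE
}
setValidity("VoxelGrid", validVoxelGrid)

#' CT volume in Hounsfield units
#'
#' @slot hu 3-D numeric array of Hounsfield units (water = 0, air = -1000).
#'   Values below -1024 are clamped at construction (reconstruction dialects
#'   differ in their air floor).
#' @slot voxelSize,origin see \linkS4class{VoxelGrid}.
#' @exportClass CTVolume
setClass("CTVolume", contains = "VoxelGrid", representation(hu = "array"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@hu)) != 3L)
    msg <- c(msg, "hu must be a 3-D array")
  if (anyNA(object@hu) || any(!is.finite(object@hu)))
    msg <- c(msg, "hu must be finite")
  else if (any(object@hu < -1024))
    msg <- c(msg, "hu must be >= -1024 (clamp floor)")
  if (length(msg)) msg else TRUE
})

#' Binary segmentation volume
#'
#' @slot s 3-D array with values exactly 0 or 1 (1 = lung).
#' @slot voxelSize,origin see \linkS4class{VoxelGrid}.
#' @exportClass BinaryVolume
setClass("BinaryVolume", contains = "VoxelGrid", representation(s = "array"))

setValidity("BinaryVolume", function(object) {
  if (length(dim(object@s)) != 3L) return("s must be a 3-D array")
  if (!all(object@s == 0 | object@s == 1)) return("s must contain only 0 and 1")
  TRUE
})

#' Water-relative attenuation volume
#'
#' Per-voxel linear attenuation coefficient relative to water,
#' (HU + 1000)/1000; dimensionless. After masking it is zero outside the
#' segmented lung.
#'
#' @slot m 3-D numeric array of relative attenuation values.
#' @slot voxelSize,origin see \linkS4class{VoxelGrid}.
#' @exportClass AttenuationVolume
setClass("AttenuationVolume", contains = "VoxelGrid",
         representation(m = "array"))

setValidity("AttenuationVolume", function(object) {
  if (length(dim(object@m)) != 3L) return("m must be a 3-D array")
  if (any(!is.finite(object@m))) return("m must be finite")
  TRUE
})

#' Cone-beam projection geometry
#'
#' Source position, detector frame and the rigid pose of the volume, all in
#' mm in a common geometry frame. Detector pixel (0, 0) sits at
#' \code{detectorOrigin}; pixel (i, j) at
#' \code{detectorOrigin + i * pixelPitch * axis1 + j * pixelPitch * axis2}.
#' The pose maps volume-frame coordinates into the geometry frame:
#' x_geo = rotation \%*\% x_vol + translation.
#'
#' @slot sourcePosition numeric(3), mm.
#' @slot detectorOrigin numeric(3), mm (center of pixel (0, 0)).
#' @slot detectorAxes 3 x 2 matrix of orthonormal in-plane unit vectors.
#' @slot pixelPitch numeric(1), mm.
#' @slot detectorShape integer(2), pixel counts along the two axes.
#' @slot volumeRotation 3 x 3 rotation matrix of the volume pose.
#' @slot volumeTranslation numeric(3), mm.
#' @exportClass ProjectionGeometry
setClass("ProjectionGeometry", representation(
  sourcePosition = "numeric", detectorOrigin = "numeric",
  detectorAxes = "matrix", pixelPitch = "numeric",
  detectorShape = "integer", volumeRotation = "matrix",
  volumeTranslation = "numeric"))

setValidity("ProjectionGeometry", function(object) {
  msg <- character()
  ax <- object@detectorAxes
  if (!all(dim(ax) == c(3L, 2L)))
    msg <- c(msg, "detectorAxes must be a 3 x 2 matrix")
  else {
    g <- crossprod(ax)
    if (max(abs(g - diag(2))) > 1e-8)
      msg <- c(msg, "detector axes must be orthonormal")
    nrm <- c(ax[2, 1] * ax[3, 2] - ax[3, 1] * ax[2, 2],
             ax[3, 1] * ax[1, 2] - ax[1, 1] * ax[3, 2],
             ax[1, 1] * ax[2, 2] - ax[2, 1] * ax[1, 2])
    if (abs(sum((object@sourcePosition - object@detectorOrigin) * nrm)) < 1e-6)
      msg <- c(msg, "source must not lie in the detector plane")
  }
  if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive value (mm)")
  if (length(object@detectorShape) != 2L || any(object@detectorShape < 1L))
    msg <- c(msg, "detectorShape must be two positive pixel counts")
  R <- object@volumeRotation
  if (!all(dim(R) == c(3L, 3L)) || max(abs(crossprod(R) - diag(3))) > 1e-8)
    msg <- c(msg, "volumeRotation must be a 3 x 3 rotation matrix")
  if (length(msg)) msg else TRUE
})

#' Projected thickness map
#'
#' Line integrals of a volume in the radiograph frame: either projected lung
#' thickness d_lung (mm of lung along each source-pixel ray) or
#' water-equivalent height d_h2o (mm of water with the same attenuation).
#'
#' @slot values numeric matrix, mm; indexed [detector axis 1, detector axis 2].
#' @slot kind one of "d_lung", "d_h2o", "generic".
#' @slot pixelPitch detector pixel pitch, mm.
#' @exportClass ProjectionMap
setClass("ProjectionMap", representation(
  values = "matrix", kind = "character", pixelPitch = "numeric"))

setValidity("ProjectionMap", function(object) {
  msg <- character()
  if (!object@kind %in% c("d_lung", "d_h2o", "generic"))
    msg <- c(msg, "kind must be 'd_lung', 'd_h2o' or 'generic'")
  if (object@kind != "generic") {
    v <- object@values
    if (any(!is.finite(v)))
      msg <- c(msg, "thickness values must be finite")
    else if (any(v < 0))
      msg <- c(msg, "thickness values must be >= 0")
  }
  if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive value (mm)")
  if (length(msg)) msg else TRUE
})

#' Registered radiograph set
#'
#' Registered per-pixel maps from one dark-field acquisition: transmittance T,
#' visibility reduction nu, the beam-hardening-corrected dark-field signal D
#' (filled by \code{\link{correctBeamHardening}}), and the flat-field photon
#' count and visibility maps entering the shot-noise model.
#'
#' @slot tMap transmittance per pixel, in (0, 1] (values marginally above 1
#'   are tolerated up to 1.05 for shot-noise fluctuation at unit
#'   transmittance).
#' @slot nuMap visibility reduction per pixel, > 0.
#' @slot dMap corrected dark-field signal per pixel, or NULL before correction.
#' @slot flatIntensity flat-field photon count I_r per pixel, > 0.
#' @slot flatVisibility flat-field visibility V_r per pixel, in (0, 1).
#' @exportClass RadiographSet
setClass("RadiographSet", representation(
  tMap = "matrix", nuMap = "matrix", dMap = "matrixOrNULL",
  flatIntensity = "matrix", flatVisibility = "matrix"))

setValidity("RadiographSet", function(object) {
  msg <- character()
  dm <- dim(object@tMap)
  for (nm in c("nuMap", "flatIntensity", "flatVisibility"))
    if (!identical(dim(slot(object, nm)), dm))
      msg <- c(msg, sprintf("%s must match the shape of tMap", nm))
  if (!is.null(object@dMap) && !identical(dim(object@dMap), dm))
    msg <- c(msg, "dMap must match the shape of tMap")
  if (any(object@tMap <= 0) || any(object@tMap > 1.05))
    msg <- c(msg, "transmittance must lie in (0, 1]")
  if (any(object@nuMap <= 0))
    msg <- c(msg, "visibility reduction must be > 0")
  if (any(object@flatIntensity <= 0))
    msg <- c(msg, "flat-field intensity must be > 0")
  if (any(object@flatVisibility <= 0) || any(object@flatVisibility >= 1))
    msg <- c(msg, "flat-field visibility must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Beam-hardening calibration curve
#'
#' Per-detector-column interpolants mapping transmittance to the secondary
#' (beam-hardening plus Compton) visibility reduction, built from
#' polyoxymethylene absorber stacks of known heights.
#'
#' @slot heights absorber heights d_k in mm, strictly increasing.
#' @slot tNodes heights x columns matrix of y-averaged calibration
#'   transmittances.
#' @slot nuNodes heights x columns matrix of y-averaged calibration
#'   visibility reductions.
#' @slot funs list of per-column interpolants nu_int(T) (monotone cubic in T,
#'   constant beyond the node range).
#' @exportClass CalibrationCurve
setClass("CalibrationCurve", representation(
  heights = "numeric", tNodes = "matrix", nuNodes = "matrix", funs = "list"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@heights) < 2L || any(diff(object@heights) <= 0))
    msg <- c(msg, "at least two strictly increasing heights are required")
  if (any(object@tNodes <= 0) || any(object@tNodes > 1))
    msg <- c(msg, "calibration transmittance nodes must lie in (0, 1]")
  if (length(object@funs) != ncol(object@tNodes))
    msg <- c(msg, "one interpolant per detector column is required")
  if (length(msg)) msg else TRUE
})

#' Compton-offset model
#'
#' Ratios of Compton-scattered to unscattered detected intensity in the
#' sample scan and in the calibration scan; their mismatch produces a
#' constant additive offset Delta in -ln D.
#'
#' @slot sampleRatio I_C / I_U in the sample scan, >= 0.
#' @slot calibRatio I_C / I_U in the calibration scan, >= 0.
#' @exportClass ComptonModel
setClass("ComptonModel", representation(
  sampleRatio = "numeric", calibRatio = "numeric"))

setValidity("ComptonModel", function(object) {
  if (length(object@sampleRatio) != 1L || object@sampleRatio < 0 ||
      length(object@calibRatio) != 1L || object@calibRatio < 0)
    return("intensity ratios must be single values >= 0")
  TRUE
})

#' Detected X-ray spectrum model
#'
#' Tungsten-anode tube spectrum in 1 keV bins after filtration, together with
#' the detector absorption and weighting that turn it into detected signal.
#'
#' @slot energyGrid bin centers in keV.
#' @slot fluence relative photons per bin after tube and added filtration;
#'   zero above the tube voltage.
#' @slot detectorAbsorption per-bin absorbed fraction in the scintillator,
#'   in [0, 1].
#' @slot energyIntegrating logical; TRUE multiplies each absorbed bin by its
#'   photon energy (flat-panel signal model).
#' @slot kv tube voltage in kV.
#' @slot filtration named numeric vector of filter thicknesses in mm.
#' @exportClass SpectrumModel
setClass("SpectrumModel", representation(
  energyGrid = "numeric", fluence = "numeric",
  detectorAbsorption = "numeric", energyIntegrating = "logical",
  kv = "numeric", filtration = "numeric"))

setValidity("SpectrumModel", function(object) {
  msg <- character()
  n <- length(object@energyGrid)
  if (length(object@fluence) != n || length(object@detectorAbsorption) != n)
    msg <- c(msg, "fluence and detectorAbsorption must match the energy grid")
  if (any(object@fluence < 0)) msg <- c(msg, "fluence must be >= 0")
  if (any(object@fluence[object@energyGrid > object@kv] > 0))
    msg <- c(msg, "fluence must vanish above the tube voltage")
  if (any(object@detectorAbsorption < 0 | object@detectorAbsorption > 1))
    msg <- c(msg, "absorbed fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Effective water attenuation coefficient
#'
#' Slope of logarithmic transmittance versus water height for a detected
#' spectrum, with the regression quality and the height range used.
#'
#' @slot muEff effective linear attenuation coefficient, 1/m; > 0.
#' @slot rSquared coefficient of determination of the height regression.
#' @slot maxHeight largest water height used, mm.
#' @slot maxResidual largest absolute residual of -ln T (beam-hardening
#'   nonlinearity).
#' @exportClass EffectiveMu
setClass("EffectiveMu", representation(
  muEff = "numeric", rSquared = "numeric", maxHeight = "numeric",
  maxResidual = "numeric"))

setValidity("EffectiveMu", function(object) {
  if (length(object@muEff) != 1L || !is.finite(object@muEff) ||
      object@muEff <= 0)
    return("muEff must be a single positive value (1/m)")
  TRUE
})

#' Weighted pixelwise regression fit
#'
#' Result of regressing -ln D on a projected thickness map. The slope against
#' d_lung is the lung-mean dark-field extinction coefficient; against d_h2o
#' it is the dark-field signal per water-equivalent height.
#'
#' @slot slope 1/m.
#' @slot intercept dimensionless (estimate of the Compton offset Delta).
#' @slot rSquared weighted coefficient of determination, <= 1.
#' @slot nPixels number of included pixels, >= 2.
#' @slot xKind "d_lung" or "d_h2o".
#' @slot slopeSE,interceptSE standard errors (slope in 1/m).
#' @exportClass RegressionFit
setClass("RegressionFit", representation(
  slope = "numeric", intercept = "numeric", rSquared = "numeric",
  nPixels = "integer", xKind = "character",
  slopeSE = "numeric", interceptSE = "numeric"))

setValidity("RegressionFit", function(object) {
  msg <- character()
  if (object@nPixels < 2L) msg <- c(msg, "at least two pixels are required")
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared cannot exceed 1")
  if (!object@xKind %in% c("d_lung", "d_h2o"))
    msg <- c(msg, "xKind must be 'd_lung' or 'd_h2o'")
  if (length(msg)) msg else TRUE
})

#' Power-law fit y = a V^b
#'
#' Log-log least-squares fit of a coefficient against lung volume.
#'
#' @slot a prefactor (> 0).
#' @slot b exponent, dimensionless.
#' @exportClass PowerLawFit
setClass("PowerLawFit", representation(a = "numeric", b = "numeric"))

#' Noise level estimate
#'
#' Standard deviations of ln D and ln T and their ratio, either measured in a
#' region of interest or predicted by the shot-noise model.
#'
#' @slot sigmaLnD,sigmaLnT standard deviations, >= 0.
#' @slot ratio sigma(ln D) / sigma(ln T); NaN if sigma(ln T) = 0.
#' @slot source "measured_roi" or "theoretical".
#' @exportClass NoiseEstimate
setClass("NoiseEstimate", representation(
  sigmaLnD = "numeric", sigmaLnT = "numeric", ratio = "numeric",
  source = "character"))

setValidity("NoiseEstimate", function(object) {
  msg <- character()
  if (object@sigmaLnD < 0 || object@sigmaLnT < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (!object@source %in% c("measured_roi", "theoretical"))
    msg <- c(msg, "source must be 'measured_roi' or 'theoretical'")
  if (length(msg)) msg else TRUE
})

#' CNR summary
#'
#' Normalized scatter, noise-level ratio and their quotient, the ratio of
#' dark-field to attenuation contrast-to-noise ratios for a small difference
#' in lung thickness.
#'
#' @slot normalizedScatter dimensionless.
#' @slot noiseRatio sigma(ln D) / sigma(ln T), dimensionless.
#' @slot cnrRatio normalizedScatter / noiseRatio.
#' @exportClass CnrSummary
setClass("CnrSummary", representation(
  normalizedScatter = "numeric", noiseRatio = "numeric",
  cnrRatio = "numeric"))

setValidity("CnrSummary", function(object) {
  if (abs(object@cnrRatio - object@normalizedScatter / object@noiseRatio) >
      1e-10 * max(1, abs(object@cnrRatio)))
    return("cnrRatio must equal normalizedScatter / noiseRatio")
  TRUE
})

#' Digital thorax phantom specification
#'
#' Geometry, ventilation state, ground-truth signal parameters and
#' acquisition statistics of the synthetic thorax. See
#' \code{\link{phantomSpec}} for defaults and units.
#'
#' @slot bodySemiAxes mm triple of the body ellipsoid semi-axes.
#' @slot lungSemiAxes 3 x 2 matrix, per-lung semi-axes in mm.
#' @slot lungCenters 3 x 2 matrix, per-lung center in mm.
#' @slot ventilationState "low", "mid" or "high".
#' @slot lungMeanHU mean Hounsfield value of lung voxels.
#' @slot textureSD standard deviation of the lung HU jitter (HU).
#' @slot bronchus logical, carve an air cylinder into the right lung.
#' @slot muDTrue dark-field extinction coefficient inside the lung, 1/m.
#' @slot deltaTrue Compton intercept Delta, dimensionless.
#' @slot bhFraction ratio -ln(nu_sec) / -ln(T), dimensionless.
#' @slot muEffSim effective water attenuation of the simulated acquisition
#'   spectrum, 1/m.
#' @slot fluxRef flat-field photons per pixel.
#' @slot visibilityRef flat-field visibility, in (0, 1).
#' @slot voxelSize mm triple of the phantom CT voxel size.
#' @slot seed integer seed driving all phantom randomness.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  bodySemiAxes = "numeric", lungSemiAxes = "matrix", lungCenters = "matrix",
  ventilationState = "character", lungMeanHU = "numeric",
  textureSD = "numeric", bronchus = "logical",
  muDTrue = "numeric", deltaTrue = "numeric", bhFraction = "numeric",
  muEffSim = "numeric", fluxRef = "numeric", visibilityRef = "numeric",
  voxelSize = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@ventilationState %in% c("low", "mid", "high"))
    msg <- c(msg, "ventilationState must be 'low', 'mid' or 'high'")
  if (object@visibilityRef <= 0 || object@visibilityRef >= 1)
    msg <- c(msg, "visibilityRef must lie in (0, 1)")
  if (object@fluxRef <= 0) msg <- c(msg, "fluxRef must be > 0")
  if (object@muDTrue < 0) msg <- c(msg, "muDTrue must be >= 0")
  if (any(object@lungSemiAxes < 0))
    msg <- c(msg, "lung semi-axes must be >= 0")
  # lungs strictly inside the body ellipsoid (axis-aligned bound check)
  for (l in 1:2) {
    ext <- abs(object@lungCenters[, l]) + object@lungSemiAxes[, l]
    if (any(ext >= object@bodySemiAxes))
      msg <- c(msg, "lung ellipsoids must lie strictly inside the body")
  }
  thr <- segmentationThresholds(stateToPreset(object@ventilationState))
  if (object@lungMeanHU <= thr@lLow || object@lungMeanHU >= thr@lHigh)
    msg <- c(msg, sprintf(
      "lungMeanHU must lie inside the '%s' segmentation window (%g, %g)",
      object@ventilationState, thr@lLow, thr@lHigh))
  if (length(msg)) msg else TRUE
})

#' Phantom ground truth
#'
#' Per-voxel ground-truth fields the radiograph generator projects, plus the
#' scalar truths the pipeline is expected to recover.
#'
#' @slot muDField per-voxel dark-field extinction coefficient, 1/m; nonzero
#'   only inside lung compartments.
#' @slot densityField per-voxel attenuation relative to water (air 0, soft
#'   tissue 1, lung parenchyma in between).
#' @slot lungMask per-voxel lung indicator array (0/1).
#' @slot lungVolumeTrue segmented-lung volume in liters.
#' @slot deltaTrue,bhFraction,muEffSim copied from the spec.
#' @slot voxelSize,origin see \linkS4class{VoxelGrid}.
#' @exportClass PhantomTruth
setClass("PhantomTruth", contains = "VoxelGrid", representation(
  muDField = "array", densityField = "array", lungMask = "array",
  lungVolumeTrue = "numeric", deltaTrue = "numeric", bhFraction = "numeric",
  muEffSim = "numeric"))

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (any(object@muDField[object@lungMask == 0] != 0))
    msg <- c(msg, "muDField must be nonzero only inside the lung")
  if (any(object@densityField < 0) || any(object@densityField > 1.1))
    msg <- c(msg, "densityField must lie in [0, 1.1]")
  if (length(msg)) msg else TRUE
})

#' Segmentation thresholds
#'
#' Hounsfield window (strict inequalities on both sides) bounding lung
#' voxels. Presets: "inspiration" (-922, -512) for mid and high ventilation
#' pressure, "expiration" (-870, -410) for low pressure.
#'
#' @slot lLow,lHigh window bounds in HU, lLow < lHigh.
#' @exportClass SegmentationThresholds
setClass("SegmentationThresholds", representation(
  lLow = "numeric", lHigh = "numeric"))

setValidity("SegmentationThresholds", function(object) {
  if (length(object@lLow) != 1L || length(object@lHigh) != 1L ||
      object@lLow >= object@lHigh)
    return("lLow must be smaller than lHigh")
  TRUE
})
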