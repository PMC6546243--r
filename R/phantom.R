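# Digital thorax phantom: CT volume, ground truth, registered radiographs
# and POM calibration stacks with the statistical structure the analysis
# assumes.

# ventilation states: total lung volume (l) and mean lung HU chosen so that
# lung mass (density * volume) is conserved across states, emulating the
# same lung at three airway pressures
.ventilationStates <- data.frame(
  state = c("low", "mid", "high"),
  volume_l = c(0.76, 1.20, 1.37),
  mean_hu = c(-640, -772, -800))

#' Digital thorax phantom specification
#'
#' An ellipsoidal body (soft tissue, 0 HU) in air (-1000 HU) containing two
#' ellipsoidal lung compartments whose size and mean Hounsfield value are
#' tied to a ventilation state: "low" (simulated expiration, 0.76 l at
#' -640 HU), "mid" (1.20 l, -772 HU) and "high" (full inspiration, 1.37 l,
#' -800 HU). Mean lung density scales inversely with lung volume, so lung
#' mass is conserved across states. Lung voxels get Gaussian HU texture
#' (default sigma 30 HU) clipped to the matching segmentation window.
#'
#' @param ventilationState "low", "mid" or "high".
#' @param muDTrue dark-field extinction coefficient inside the lung, 1/m
#'   (default 4.0).
#' @param deltaTrue Compton intercept Delta (default -0.05).
#' @param bhFraction ratio of logarithmic secondary visibility reduction to
#'   logarithmic transmittance (default 0.10).
#' @param muEffSim effective water attenuation coefficient of the simulated
#'   acquisition spectrum, 1/m; by default computed from the package's
#'   60 kV gratings spectral scenario.
#' @param fluxRef flat-field photons per pixel (default 1e4).
#' @param visibilityRef flat-field visibility (default 0.365).
#' @param voxelSize phantom CT voxel size in mm (default 4 mm isotropic).
#' @param textureSD lung HU jitter standard deviation (default 30 HU).
#' @param bronchus carve an air cylinder into the right lung to exercise
#'   airway exclusion (default FALSE).
#' @param lungScale extra multiplier on the lung semi-axes (default 1; used
#'   for edge cases such as empty lungs with \code{lungScale = 0}).
#' @param lungMeanHU override of the state's mean lung HU.
#' @param seed integer seed for all phantom randomness.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(ventilationState = c("high", "mid", "low"),
                        muDTrue = 4.0, deltaTrue = -0.05, bhFraction = 0.10,
                        muEffSim = NULL, fluxRef = 1e4, visibilityRef = 0.365,
                        voxelSize = c(4, 4, 4), textureSD = 30,
                        bronchus = FALSE, lungScale = 1,
                        lungMeanHU = NULL, seed = 1L) {
  ventilationState <- match.arg(ventilationState)
  st <- .ventilationStates[.ventilationStates$state == ventilationState, ]
  if (is.null(lungMeanHU)) lungMeanHU <- st$mean_hu
  if (is.null(muEffSim)) muEffSim <- defaultMuEffSim()
  # per-lung semi-axes of the 'low' state, scaled isotropically with volume
  base <- c(36, 42, 60)
  sc <- (st$volume_l / 0.76)^(1 / 3) * lungScale
  semi <- cbind(base * sc, base * sc)
  centers <- cbind(c(-55, 0, 0), c(55, 0, 0))
  new("PhantomSpec",
      bodySemiAxes = c(115, 85, 125), lungSemiAxes = semi,
      lungCenters = centers, ventilationState = ventilationState,
      lungMeanHU = as.numeric(lungMeanHU), textureSD = textureSD,
      bronchus = bronchus, muDTrue = muDTrue, deltaTrue = deltaTrue,
      bhFraction = bhFraction, muEffSim = muEffSim, fluxRef = fluxRef,
      visibilityRef = visibilityRef, voxelSize = as.numeric(voxelSize),
      seed = as.integer(seed))
}

.muEffSimCache <- new.env(parent = emptyenv())

# effective water attenuation of the 60 kV gratings scenario, cached
defaultMuEffSim <- function() {
  if (is.null(.muEffSimCache$value)) {
    sp <- simulateDetectedSpectrum(60, gratingFilter = c(Si = 1.5))
    .muEffSimCache$value <- muEff(effectiveMuWater(sp))
  }
  .muEffSimCache$value
}

#' Generate the phantom CT volume and ground truth
#'
#' Builds the Hounsfield volume (air -1000, body 0, textured lung voxels
#' inside the state's segmentation window) and the matching ground truth:
#' the per-voxel dark-field extinction field (uniform muDTrue inside the
#' lung), the water-relative density field (HU + 1000) / 1000, the lung
#' indicator and the true lung volume. With \code{bronchus = TRUE} an air
#' cylinder (radius 8 mm) is carved into the right lung; its interior falls
#' outside the Hounsfield window and does not count as lung.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{ct} (\linkS4class{CTVolume}) and
#'   \code{truth} (\linkS4class{PhantomTruth}).
#' @export
generatePhantomCT <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  margin <- 8
  ext <- spec@bodySemiAxes + margin
  dims <- as.integer(ceiling(2 * ext / spec@voxelSize))
  org <- -(dims - 1) / 2 * spec@voxelSize
  x <- org[1] + (seq_len(dims[1]) - 1) * spec@voxelSize[1]
  y <- org[2] + (seq_len(dims[2]) - 1) * spec@voxelSize[2]
  z <- org[3] + (seq_len(dims[3]) - 1) * spec@voxelSize[3]
  X <- array(x, dims)
  Y <- array(rep(y, each = dims[1]), dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dims)
  B <- spec@bodySemiAxes
  body <- (X / B[1])^2 + (Y / B[2])^2 + (Z / B[3])^2 <= 1
  lung <- array(FALSE, dims)
  for (l in 1:2) {
    a <- spec@lungSemiAxes[, l]
    if (any(a <= 0)) next
    cc <- spec@lungCenters[, l]
    lung <- lung | (((X - cc[1]) / a[1])^2 + ((Y - cc[2]) / a[2])^2 +
                    ((Z - cc[3]) / a[3])^2 <= 1)
  }
  if (any(lung & !body))
    stop("invalid phantom spec: lung extends outside the body")
  # the lung compartment is the morphological closure of the voxelized
  # ellipsoids: segmentation applies the same closing, so thresholding the
  # phantom recovers the compartment exactly
  lung <- closing3d(array(as.numeric(lung), dims)) == 1
  bronchus <- array(FALSE, dims)
  if (spec@bronchus) {
    cc <- spec@lungCenters[, 2]
    a <- spec@lungSemiAxes[, 2]
    bronchus <- ((X - cc[1])^2 + (Y - cc[2])^2 <= 8^2) &
      abs(Z - cc[3]) <= a[3] & lung
  }
  hu <- array(-1000, dims)
  hu[body] <- 0
  thr <- segmentationThresholds(stateToPreset(spec@ventilationState))
  nLung <- sum(lung & !bronchus)
  set.seed(spec@seed)
  hvals <- rnorm(nLung, spec@lungMeanHU, spec@textureSD)
  hvals <- pmin(pmax(hvals, thr@lLow + 1), thr@lHigh - 1)
  hu[lung & !bronchus] <- hvals
  hu[bronchus] <- -1000
  mask <- array(as.numeric(lung & !bronchus), dims)
  density <- (hu + 1000) / 1000
  truth <- new("PhantomTruth",
               muDField = spec@muDTrue * mask, densityField = density,
               lungMask = mask,
               lungVolumeTrue = sum(mask) * prod(spec@voxelSize) / 1e6,
               deltaTrue = spec@deltaTrue, bhFraction = spec@bhFraction,
               muEffSim = spec@muEffSim, voxelSize = spec@voxelSize,
               origin = org)
  list(ct = ctVolume(hu, spec@voxelSize, org), truth = truth)
}

#' Project the phantom ground-truth fields
#'
#' Noise-free reference maps in the radiograph frame: projected lung
#' thickness (from the lung indicator), water-equivalent height of the whole
#' body and of the lung alone (from the density field).
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param geometry a \linkS4class{ProjectionGeometry}.
#' @return list of \linkS4class{ProjectionMap}s \code{dLung}, \code{dH2O}
#'   (whole body) and \code{dH2OLung}.
#' @export
projectTruth <- function(truth, geometry) {
  stopifnot(is(truth, "PhantomTruth"))
  asBin <- new("BinaryVolume", s = truth@lungMask,
               voxelSize = truth@voxelSize, origin = truth@origin)
  asAtt <- function(a) new("AttenuationVolume", m = a,
                           voxelSize = truth@voxelSize,
                           origin = truth@origin)
  list(dLung = forwardProject(asBin, geometry),
       dH2O = forwardProject(asAtt(truth@densityField), geometry),
       dH2OLung = forwardProject(asAtt(truth@densityField * truth@lungMask),
                                 geometry))
}

#' Generate registered phantom radiographs
#'
#' Noise-free construction: the logarithmic corrected dark-field signal is
#' the line integral of the extinction field plus the Compton intercept,
#' -ln D = int mu_d dl + Delta; logarithmic transmittance is the
#' water-equivalent body height times the simulated effective water
#' attenuation, -ln T = muEffSim d_h2o; and the measured visibility
#' reduction is nu = D nu_sec with -ln nu_sec = bhFraction (-ln T). With
#' \code{noise = TRUE}, per-pixel Gaussian perturbations with the
#' phase-stepping shot-noise sigmas (sigma(D) from the dark-field variance
#' model at the flat-field statistics; sigma(ln T)^2 = (1 + 1/T) / I^r) are
#' applied to D and T in the log domain, using the same linearization
#' sigma(ln X) = sigma(X)/X as the noise-ratio analysis, so the corrected
#' signal carries the noise the regression weights assume while the log
#' signals stay unbiased. Noisy transmittance estimates are truncated at
#' unity.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param geometry a \linkS4class{ProjectionGeometry}.
#' @param spec the generating \linkS4class{PhantomSpec} (flat-field
#'   statistics, seed).
#' @param noise add shot noise (default FALSE).
#' @return a \linkS4class{RadiographSet}.
#' @export
generatePhantomRadiographs <- function(truth, geometry, spec,
                                       noise = FALSE) {
  stopifnot(is(truth, "PhantomTruth"), is(spec, "PhantomSpec"))
  if (noise && spec@fluxRef <= 0)
    stop("invalid spec: noise requires a positive flat-field flux")
  asAtt <- function(a) new("AttenuationVolume", m = a,
                           voxelSize = truth@voxelSize,
                           origin = truth@origin)
  intMuD <- mapValues(forwardProject(asAtt(truth@muDField), geometry)) / 1000
  dH2O <- mapValues(forwardProject(asAtt(truth@densityField), geometry))
  lnD <- -(intMuD + truth@deltaTrue)
  lnT <- -truth@muEffSim * dH2O / 1000
  D <- exp(lnD)
  T <- exp(lnT)
  if (noise) {
    set.seed(spec@seed + 499979L)
    # Gaussian perturbations in the log domain with the shot-noise sigmas
    # sigma(ln X) = sigma(X)/X; to first order the variances of D and T
    # match the stepping noise model, and the log signals the regression
    # consumes stay unbiased
    sdLnD <- sqrt(darkFieldVariance(D, T, spec@visibilityRef,
                                    spec@fluxRef)) / D
    sdLnT <- sqrt((1 + 1 / T) / spec@fluxRef)
    D <- D * exp(array(rnorm(length(D)), dim(D)) * sdLnD)
    T <- T * exp(array(rnorm(length(T)), dim(T)) * sdLnT)
    T <- pmin(T, 1)
  }
  nuSec <- exp(-truth@bhFraction * (-log(T)))
  radiographSet(tMap = T, nuMap = D * nuSec,
                flatIntensity = spec@fluxRef,
                flatVisibility = spec@visibilityRef)
}

#' Generate a POM calibration stack
#'
#' Per-height transmittance and visibility-reduction maps for a stack of
#' homogeneous polyoxymethylene absorbers: T falls with height following
#' Beer-Lambert at the simulated effective attenuation (POM attenuation
#' relative to water \code{pomRelMu}), and the secondary visibility
#' reduction follows -ln nu = bhFraction (-ln T). POM produces no
#' small-angle scatter, so nu contains only the secondary effects.
#'
#' @param heights POM heights in mm, strictly increasing, >= 2 entries.
#'   The default ladder (0 to 160 mm in 16 mm steps) starts at the blank
#'   scan and spans the transmittance range of a thorax acquisition densely
#'   enough that interpolation error is negligible against shot noise.
#' @param geometry a \linkS4class{ProjectionGeometry} fixing the detector
#'   shape.
#' @param spec a \linkS4class{PhantomSpec} (bhFraction, muEffSim).
#' @param pomRelMu POM attenuation relative to water (default 1.33).
#' @return list with \code{heights}, \code{tCal} and \code{nuCal} (lists of
#'   per-height matrices), ready for \code{\link{buildCalibration}}.
#' @export
generateCalibrationStack <- function(heights = seq(0, 160, by = 16),
                                     geometry, spec, pomRelMu = 1.33) {
  if (length(heights) < 2L)
    stop("insufficient calibration: at least 2 POM heights are required")
  if (any(diff(heights) <= 0))
    stop("POM heights must be strictly increasing")
  shape <- geometry@detectorShape
  tCal <- nuCal <- vector("list", length(heights))
  for (k in seq_along(heights)) {
    lnT <- spec@muEffSim * pomRelMu * heights[k] / 1000
    tCal[[k]] <- matrix(exp(-lnT), shape[1], shape[2])
    nuCal[[k]] <- matrix(exp(-spec@bhFraction * lnT), shape[1], shape[2])
  }
  list(heights = heights, tCal = tCal, nuCal = nuCal)
}
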