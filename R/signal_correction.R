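# Visibility extraction, POM beam-hardening correction, Compton offset.

#' Construct a registered radiograph set
#'
#' @param tMap transmittance matrix, values in (0, 1].
#' @param nuMap visibility-reduction matrix, values > 0.
#' @param flatIntensity flat-field photon count per pixel; a scalar is
#'   expanded to the map shape.
#' @param flatVisibility flat-field visibility per pixel in (0, 1); a scalar
#'   is expanded.
#' @param dMap optional corrected dark-field map (normally filled later by
#'   \code{\link{correctBeamHardening}}).
#' @return a \linkS4class{RadiographSet}.
#' @export
radiographSet <- function(tMap, nuMap, flatIntensity, flatVisibility,
                          dMap = NULL) {
  d <- dim(tMap)
  expand <- function(x) if (length(x) == 1L) matrix(x, d[1], d[2]) else x
  new("RadiographSet", tMap = tMap, nuMap = nuMap, dMap = dMap,
      flatIntensity = expand(flatIntensity),
      flatVisibility = expand(flatVisibility))
}

#' Interferometric visibility from phase-stepping intensities
#'
#' Least-squares fit of the sinusoidal stepping model
#' I(phi) = a + b cos(phi + phi0); the visibility is |b| / a. For an exact
#' sinusoid this equals (Imax - Imin) / (Imax + Imin).
#'
#' @param intensities intensity samples (>= 3).
#' @param phases grating phases in radians, spanning a period.
#' @return visibility in [0, 1] for physical signals.
#' @export
visibilityFromStepping <- function(intensities, phases) {
  if (length(intensities) < 3L || length(intensities) != length(phases))
    stop("at least 3 intensity samples with matching phases are required")
  X <- cbind(1, cos(phases), sin(phases))
  beta <- qr.solve(X, intensities)
  if (beta[1] <= 0) stop("invalid stepping signal: non-positive mean intensity")
  sqrt(beta[2]^2 + beta[3]^2) / beta[1]
}

#' Build a beam-hardening calibration curve
#'
#' From calibration records at increasing polyoxymethylene heights, the
#' (T, nu) maps are averaged along the scanning direction (second map index)
#' to one node per detector column and height; each column then gets a
#' shape-preserving monotone cubic interpolant nu_int(T) through its nodes,
#' with constant extrapolation beyond the node range. Monotone interpolation
#' is used so the correction cannot overshoot between calibration nodes.
#'
#' @param records list with elements \code{heights} (mm, strictly
#'   increasing, >= 2 entries), \code{tCal} and \code{nuCal} (lists of
#'   per-height matrices, detector column in the first index), as produced
#'   by \code{\link{generateCalibrationStack}} or read from files.
#' @return a \linkS4class{CalibrationCurve}.
#' @export
buildCalibration <- function(records) {
  h <- records$heights
  if (length(h) < 2L)
    stop("insufficient calibration: at least 2 absorber heights are required")
  if (any(diff(h) <= 0)) stop("calibration heights must be strictly increasing")
  nCol <- nrow(records$tCal[[1]])
  tNodes <- t(vapply(records$tCal, rowMeans, numeric(nCol)))
  nuNodes <- t(vapply(records$nuCal, rowMeans, numeric(nCol)))
  # transmittance must fall with absorber height in every column
  if (any(apply(tNodes, 2, function(tc) any(diff(tc) >= 0))))
    stop("calibration inconsistency: averaged T does not decrease with height")
  valid <- apply(tNodes, 2, function(tc) sum(is.finite(tc)) >= 2L)
  if (!any(valid)) stop("no detector column has enough calibration nodes")
  if (!all(valid))
    message(sprintf(
      "%d detector columns lack calibration nodes; inheriting neighbours",
      sum(!valid)))
  mkfun <- function(x) {
    tc <- tNodes[, x]
    nu <- nuNodes[, x]
    o <- order(tc)
    tc <- tc[o]
    nu <- nu[o]
    lo <- tc[1]
    hi <- tc[length(tc)]
    f <- if (length(unique(nu)) == 1L) {
      nu0 <- nu[1]
      function(v) rep(nu0, length(v))
    } else splinefun(tc, nu, method = "monoH.FC")
    function(v) f(pmin(pmax(v, lo), hi))
  }
  funs <- vector("list", nCol)
  validIdx <- which(valid)
  for (x in seq_len(nCol)) {
    src <- validIdx[which.min(abs(validIdx - x))]
    funs[[x]] <- mkfun(src)
  }
  new("CalibrationCurve", heights = h, tNodes = tNodes, nuNodes = nuNodes,
      funs = funs)
}

#' Evaluate a calibration curve
#'
#' Secondary visibility reduction nu_sec for given transmittances in one
#' detector column.
#'
#' @param cal a \linkS4class{CalibrationCurve}.
#' @param tValues transmittance values.
#' @param column detector column index (1-based).
#' @return nu_sec values.
#' @export
evalCalibration <- function(cal, tValues, column = 1L) {
  cal@funs[[column]](tValues)
}

#' Beam-hardening correction of visibility reduction
#'
#' The measured visibility reduction is divided per pixel by the secondary
#' visibility reduction nu_sec = nu_int_x(T) evaluated from the calibration
#' curve of the pixel's detector column, yielding the corrected dark-field
#' signal D. Transmittance is returned unchanged (beam hardening of T is
#' negligible for the spectra and attenuation range this models).
#' Transmittances outside the calibrated range are corrected with the
#' constant-extrapolated curve and counted in a message.
#'
#' @param rad a \linkS4class{RadiographSet}.
#' @param cal a \linkS4class{CalibrationCurve} with one interpolant per
#'   detector column of \code{rad}.
#' @return the radiograph set with the corrected dark-field map filled in.
#' @export
correctBeamHardening <- function(rad, cal) {
  stopifnot(is(rad, "RadiographSet"), is(cal, "CalibrationCurve"))
  nCol <- nrow(rad@tMap)
  if (length(cal@funs) != nCol)
    stop("calibration covers a different detector width than the radiograph")
  nuSec <- matrix(0, nCol, ncol(rad@tMap))
  for (x in seq_len(nCol))
    nuSec[x, ] <- cal@funs[[x]](rad@tMap[x, ])
  if (any(nuSec <= 0))
    stop("correction error: non-positive secondary visibility reduction")
  tLo <- apply(cal@tNodes, 2, min)
  tHi <- apply(cal@tNodes, 2, max)
  nOut <- sum(rad@tMap < tLo | rad@tMap > tHi)
  if (nOut > 0)
    message(sprintf(
      "%d pixels outside the calibrated T range; constant extrapolation used",
      nOut))
  initialize(rad, dMap = rad@nuMap / nuSec)
}

#' Construct a Compton intensity-ratio model
#'
#' @param sampleRatio ratio of Compton-scattered to unscattered detected
#'   intensity in the sample scan, >= 0.
#' @param calibRatio the same ratio in the calibration scan, >= 0.
#' @return a \linkS4class{ComptonModel}.
#' @export
comptonModel <- function(sampleRatio, calibRatio) {
  new("ComptonModel", sampleRatio = as.numeric(sampleRatio),
      calibRatio = as.numeric(calibRatio))
}

#' Compton offset of the logarithmic dark-field signal
#'
#' Incoherently scattered background cannot carry fringe visibility, so a
#' Compton fraction I_C / I_U reduces measured visibility by
#' 1 / (1 + I_C / I_U). When the fraction differs between sample scan and
#' POM calibration scan, the corrected -ln D picks up the constant offset
#' Delta = ln[(1 + sampleRatio) / (1 + calibRatio)], which appears as the
#' regression intercept. For small ratios Delta is approximately their
#' difference.
#'
#' @param model a \linkS4class{ComptonModel}.
#' @return Delta, dimensionless.
#' @export
comptonDelta <- function(model) {
  stopifnot(is(model, "ComptonModel"))
  log((1 + model@sampleRatio) / (1 + model@calibRatio))
}
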