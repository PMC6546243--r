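# Noise statistics, shot-noise ratio model, structural decomposition,
# normalized scatter, CNR ratio and lung attenuation fraction.

#' Noise levels in a region of interest
#'
#' Sample standard deviations (unbiased, n - 1) of ln D and ln T over a
#' rectangular ROI and their ratio. With vanishing sigma(ln T) the ratio is
#' undefined and reported as NaN with a warning.
#'
#' @param lnD,lnT matrices of logarithmic dark-field and transmittance
#'   signals.
#' @param roi integer vector c(x0, x1, y0, y1) of 1-based inclusive index
#'   bounds; at least 25 pixels.
#' @return a \linkS4class{NoiseEstimate} with source "measured_roi".
#' @export
roiNoise <- function(lnD, lnT, roi) {
  d <- dim(lnD)
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > d[1] || roi[4] > d[2] ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("ROI outside the image")
  if ((roi[2] - roi[1] + 1) * (roi[4] - roi[3] + 1) < 25)
    stop("ROI must contain at least 25 pixels")
  sdD <- sd(lnD[roi[1]:roi[2], roi[3]:roi[4]])
  sdT <- sd(lnT[roi[1]:roi[2], roi[3]:roi[4]])
  ratio <- if (sdT == 0) {
    warning("sigma(ln T) is zero in the ROI; ratio undefined")
    NaN
  } else sdD / sdT
  new("NoiseEstimate", sigmaLnD = sdD, sigmaLnT = sdT, ratio = ratio,
      source = "measured_roi")
}

#' Theoretical shot-noise ratio sigma(ln D) / sigma(ln T)
#'
#' Ratio of the logarithmic dark-field and transmittance noise levels under
#' pure shot noise,
#' \deqn{\frac{\sigma(\ln D)}{\sigma(\ln T)} = \sqrt{1 +
#'   \frac{2\,(1 + 1/(T D^2))}{(V^r)^2\,(1 + 1/T)}},}
#' obtained by dividing the dark-field variance model by the transmittance
#' shot-noise variance sigma(ln T)^2 = (1 + 1/T) / I^r; the flat-field
#' intensity cancels. The grouping is fixed by the requirement that both
#' variances derive from the same stepping model; a Monte-Carlo propagation
#' through sinusoid extraction reproduces it (see the package tests).
#'
#' @param T transmittance in (0, 1].
#' @param D corrected dark-field signal in (0, 1] (values slightly above 1
#'   are accepted).
#' @param vRef flat-field visibility in (0, 1); the setup's measured mean is
#'   0.365.
#' @return the noise ratio (vectorized over T and D).
#' @export
shotNoiseRatio <- function(T, D, vRef = 0.365) {
  if (any(T <= 0) || any(D <= 0) || any(vRef <= 0) || any(vRef > 1) ||
      any(T > 1.05))
    stop("domain error: T, D in (0, 1] and vRef in (0, 1) required")
  sqrt(1 + 2 * (1 + 1 / (T * D^2)) / (vRef^2 * (1 + 1 / T)))
}

#' Structural-noise decomposition
#'
#' When measured noise ratios exceed the shot-noise prediction, the excess
#' is attributed to "structural" noise (unresolved sample texture). Assuming
#' shot and structural noise add in variance, the quotient of measured and
#' theoretical ratios equals sqrt((1 + s_D^2) / (1 + s_T^2)) with
#' s = sigma_struct / sigma_shot; a quotient above 1 implies the structural
#' contribution is relatively stronger in the dark-field channel.
#'
#' @param measuredRatio measured sigma(ln D) / sigma(ln T), > 0.
#' @param theoreticalRatio shot-noise prediction, > 0.
#' @return list with \code{quotient} and logical
#'   \code{structuralDarkFieldDominant}.
#' @export
structuralDecomposition <- function(measuredRatio, theoreticalRatio) {
  stopifnot(measuredRatio > 0, theoreticalRatio > 0)
  q <- measuredRatio / theoreticalRatio
  list(quotient = q, structuralDarkFieldDominant = q > 1)
}

#' Normalized scatter
#'
#' Ratio of the dark-field signal per water-equivalent height to the
#' effective water attenuation coefficient: the lung-mean ratio of
#' dark-field extinction to linear attenuation, mu_d / mu, normalized to
#' water. Equals the ratio of dark-field to attenuation contrast between
#' two regions differing only in lung thickness.
#'
#' @param slopeDH2O regression slope of -ln D versus d_h2o, 1/m.
#' @param muEff effective water attenuation coefficient of the same
#'   acquisition spectrum, 1/m; an \linkS4class{EffectiveMu} is accepted.
#' @return dimensionless normalized scatter.
#' @export
normalizedScatter <- function(slopeDH2O, muEff) {
  if (is(muEff, "EffectiveMu")) muEff <- muEff@muEff
  if (muEff <= 0) stop("muEff must be > 0")
  slopeDH2O / muEff
}

#' Ratio of dark-field to attenuation CNR
#'
#' For a small difference in lung thickness between two regions, the ratio
#' of dark-field and attenuation contrast-to-noise ratios is the normalized
#' scatter divided by the noise-level ratio sigma(ln D) / sigma(ln T).
#'
#' @param normalizedScatter dimensionless contrast ratio.
#' @param noiseRatio sigma(ln D) / sigma(ln T), > 0.
#' @return a \linkS4class{CnrSummary}.
#' @export
cnrRatio <- function(normalizedScatter, noiseRatio) {
  if (noiseRatio <= 0) stop("noiseRatio must be > 0")
  new("CnrSummary", normalizedScatter = normalizedScatter,
      noiseRatio = noiseRatio, cnrRatio = normalizedScatter / noiseRatio)
}

#' Fraction of attenuation signal due to the lung
#'
#' Multiplying the water-equivalent lung map by the effective water
#' attenuation coefficient of the acquisition spectrum gives the attenuation
#' signal of the lung alone; relating it to the measured total -ln T yields
#' the per-pixel fraction f. Pixels with ln T = 0 are undefined (NaN);
#' pixels with f outside [0, 1.05] are counted and reported in a message
#' (they indicate registration or calibration problems).
#'
#' @param dH2O water-equivalent height map (mm):
#'   \linkS4class{ProjectionMap} or matrix.
#' @param lnT matrix of ln T (<= 0 where defined).
#' @param muEff effective water attenuation coefficient at the acquisition
#'   voltage (1/m); the 60 kV gratings scenario by default matches the
#'   dark-field setup. An \linkS4class{EffectiveMu} is accepted.
#' @return matrix of fractions f with attribute \code{nOutOfRange}.
#' @export
lungAttenuationFraction <- function(dH2O, lnT, muEff) {
  if (is(dH2O, "ProjectionMap")) dH2O <- dH2O@values
  if (is(muEff, "EffectiveMu")) muEff <- muEff@muEff
  f <- (dH2O / 1000 * muEff) / (-lnT)
  f[lnT == 0] <- NaN
  nOut <- sum(f < 0 | f > 1.05, na.rm = TRUE)
  if (nOut > 0)
    message(sprintf("%d pixels with lung attenuation fraction outside [0, 1.05]",
                    nOut))
  attr(f, "nOutOfRange") <- nOut
  f
}
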