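# Pixelwise correlation of -ln D with projected thickness maps.

#' Border-exclusion mask for the regression
#'
#' The outermost lung periphery is dominated by registration error at the
#' sharp lung boundary, so pixels with a projected lung thickness below the
#' threshold are excluded; pixels with no lung (d_lung = 0) are excluded as
#' well.
#'
#' @param dLung a \linkS4class{ProjectionMap} of kind "d_lung" (or a plain
#'   matrix in mm).
#' @param threshold minimum included thickness in mm (default 3).
#' @return logical matrix, TRUE for included pixels.
#' @export
regressionMask <- function(dLung, threshold = 3) {
  v <- if (is(dLung, "ProjectionMap")) dLung@values else dLung
  v >= threshold
}

#' Shot-noise regression weights
#'
#' Per-pixel variance of the corrected dark-field signal under the
#' phase-stepping shot-noise model,
#' \deqn{\sigma(D)^2 = \frac{D^2}{(V^r)^2 I^r}\left[(V^r)^2\left(1 +
#'   \frac{1}{T}\right) + 2\left(1 + \frac{1}{T D^2}\right)\right],}
#' with weights w = 1 / sigma(D)^2, normalized to mean 1 over the included
#' pixels. The overall scale of the weights does not affect the fit; the
#' normalization only makes weight maps comparable across acquisitions.
#'
#' @param rad a corrected \linkS4class{RadiographSet} (dMap filled).
#' @param mask optional logical matrix of included pixels (used for the
#'   normalization; default all pixels).
#' @return numeric weight matrix.
#' @export
noiseWeights <- function(rad, mask = NULL) {
  stopifnot(is(rad, "RadiographSet"))
  if (is.null(rad@dMap)) stop("radiographs must be corrected first")
  D <- rad@dMap
  T <- rad@tMap
  Vr <- rad@flatVisibility
  Ir <- rad@flatIntensity
  if (any(D <= 0) || any(T <= 0) || any(Vr <= 0) || any(Ir <= 0))
    stop("weight error: non-positive D, T, V_r or I_r")
  s2 <- darkFieldVariance(D, T, Vr, Ir)
  w <- 1 / s2
  if (is.null(mask)) mask <- !is.na(w)
  w / mean(w[mask])
}

# Eq for sigma(D)^2 under phase-stepping shot noise
darkFieldVariance <- function(D, T, Vr, Ir) {
  D^2 / (Vr^2 * Ir) * (Vr^2 * (1 + 1 / T) + 2 * (1 + 1 / (T * D^2)))
}

# shot-noise variance of ln T (flat-field counts Ir, sample counts T * Ir)
logTransmittanceVariance <- function(T, Ir) (1 + 1 / T) / Ir

#' Weighted linear fit of -ln D against projected thickness
#'
#' Closed-form weighted least squares. The abscissa is in mm; the slope is
#' reported in 1/m. The weighted coefficient of determination uses the
#' weights in both the residual and total sums of squares.
#'
#' @param x thickness map (mm): \linkS4class{ProjectionMap} or matrix.
#' @param y map of -ln D (matrix).
#' @param w weight map (default unit weights).
#' @param mask logical matrix of included pixels (default all).
#' @param xKind "d_lung" or "d_h2o" (taken from a ProjectionMap input).
#' @return a \linkS4class{RegressionFit} (slope and its SE in 1/m).
#' @export
weightedLinearFit <- function(x, y, w = NULL, mask = NULL,
                              xKind = c("d_lung", "d_h2o")) {
  if (is(x, "ProjectionMap")) {
    xKind <- x@kind
    x <- x@values
  } else xKind <- match.arg(xKind)
  if (is.null(w)) w <- array(1, dim(as.matrix(x)))
  if (is.null(mask)) mask <- array(TRUE, dim(as.matrix(x)))
  xv <- x[mask]
  yv <- y[mask]
  wv <- w[mask]
  keep <- is.finite(xv) & is.finite(yv) & is.finite(wv)
  xv <- xv[keep]; yv <- yv[keep]; wv <- wv[keep]
  n <- length(xv)
  if (n < 2L) stop("at least two included pixels are required")
  if (any(wv < 0)) stop("weights must be >= 0")
  sw <- sum(wv)
  xb <- sum(wv * xv) / sw
  yb <- sum(wv * yv) / sw
  sxx <- sum(wv * (xv - xb)^2)
  if (sxx <= 0) stop("singular fit: zero weighted variance of x")
  sxy <- sum(wv * (xv - xb) * (yv - yb))
  slope_mm <- sxy / sxx
  intercept <- yb - slope_mm * xb
  res <- yv - intercept - slope_mm * xv
  ssRes <- sum(wv * res^2)
  ssTot <- sum(wv * (yv - yb)^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NaN
  mse <- ssRes / max(n - 2, 1)
  slopeSE_mm <- sqrt(mse / sxx)
  interceptSE <- sqrt(mse * (1 / sw + xb^2 / sxx))
  new("RegressionFit", slope = slope_mm * 1000, intercept = intercept,
      rSquared = r2, nPixels = as.integer(n), xKind = xKind,
      slopeSE = slopeSE_mm * 1000, interceptSE = interceptSE)
}

#' Power-law fit against lung volume
#'
#' Ordinary least squares of ln y on ln V; y = a V^b. Used to relate
#' lung-mean coefficients (dark-field extinction, relative attenuation) to
#' lung volume across ventilation states; mass conservation predicts b = -1
#' for the relative attenuation coefficient.
#'
#' @param volumes lung volumes in liters, > 0.
#' @param y coefficient values, > 0, same length.
#' @return a \linkS4class{PowerLawFit}.
#' @export
powerLawFit <- function(volumes, y) {
  if (length(volumes) < 2L || length(volumes) != length(y))
    stop("at least two (volume, y) pairs are required")
  if (any(volumes <= 0) || any(y <= 0))
    stop("power-law fit requires positive volumes and values")
  fit <- lm(log(y) ~ log(volumes))
  new("PowerLawFit", a = exp(unname(coef(fit)[1])),
      b = unname(coef(fit)[2]))
}

#' Ventilation summary table
#'
#' Per-animal table of regression slopes across ventilation pressures with
#' percent changes relative to the lowest pressure,
#' 100 (slope_p / slope_ref - 1), plus lung volumes and their percent
#' changes.
#'
#' @param fits data.frame with columns \code{animal}, \code{pressure},
#'   \code{xKind}, \code{slope} (1/m); one row per acquisition and abscissa.
#'   \linkS4class{RegressionFit} objects can be assembled into this form
#'   with \code{\link{fitSlope}}.
#' @param volumes data.frame with columns \code{animal}, \code{pressure},
#'   \code{volume} (liters); optional.
#' @return data.frame with columns animal, pressure, xKind, slope,
#'   slopeChangePct, volume, volumeChangePct, ordered by pressure within
#'   animal. Changes are relative to the lowest pressure of the same animal
#'   and abscissa.
#' @export
ventilationSummary <- function(fits, volumes = NULL) {
  stopifnot(all(c("animal", "pressure", "xKind", "slope") %in% names(fits)))
  if (length(unique(fits$pressure)) < 2L)
    stop("at least two pressure states are required")
  out <- fits[order(fits$animal, fits$xKind, fits$pressure), ]
  out$slopeChangePct <- NA_real_
  for (key in unique(paste(out$animal, out$xKind))) {
    idx <- paste(out$animal, out$xKind) == key
    ref <- out$slope[idx][which.min(out$pressure[idx])]
    out$slopeChangePct[idx] <- 100 * (out$slope[idx] / ref - 1)
  }
  if (!is.null(volumes)) {
    out$volume <- volumes$volume[match(paste(out$animal, out$pressure),
                                       paste(volumes$animal,
                                             volumes$pressure))]
    out$volumeChangePct <- NA_real_
    for (an in unique(out$animal)) {
      idx <- out$animal == an
      ref <- out$volume[idx][which.min(out$pressure[idx])]
      out$volumeChangePct[idx] <- 100 * (out$volume[idx] / ref - 1)
    }
  }
  rownames(out) <- NULL
  out
}
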