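# Pipeline orchestration: segmentation -> masking -> projection ->
# beam-hardening correction -> weighted regressions -> spectral mu_eff ->
# normalized scatter -> noise / CNR summary.

pipelineStage <- function(name, expr, log = NULL) {
  logLine <- function(msg) {
    line <- sprintf("[%s] %s", name, msg)
    message(line)
    if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  }
  res <- tryCatch(withCallingHandlers(expr, message = function(m) {
    if (!is.null(log))
      cat(sprintf("[%s] %s", name, conditionMessage(m)), file = log,
          append = TRUE)
    invokeRestart("muffleMessage")
  }), error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  list(value = res, log = logLine)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: phantom generation or file input, lung segmentation,
#' HU conversion and masking, forward projection to d_lung and d_h2o,
#' beam-hardening correction, border-exclusion masking and shot-noise
#' weighting, weighted regressions of -ln D against both thickness maps,
#' spectral simulation of the effective water attenuation, normalized
#' scatter, theoretical noise ratio at the median lung signal levels, the
#' CNR ratio and the lung attenuation fraction map. The run is
#' deterministic for a given configuration and seed.
#'
#' @param config configuration list (see \code{\link{readPipelineConfig}})
#'   or path to a YAML file.
#' @return list with the fitted \linkS4class{RegressionFit}s
#'   (\code{fitDLung}, \code{fitDH2O}), \code{lungVolume} (l),
#'   \code{muEff} (\linkS4class{EffectiveMu}), \code{cnr}
#'   (\linkS4class{CnrSummary}), \code{noiseRatio}, the maps
#'   (\code{dLung}, \code{dH2O}, \code{fMap}), the corrected
#'   \code{radiographs}, the \code{summary} data.frame, and (for phantom
#'   runs) the \code{truth}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- validatePipelineConfig(config)
  outDir <- config$output_dir
  log <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(outDir, "run.log")
    cat(sprintf("# darklung pipeline, seed %d\n", config$seed), file = log)
  }
  st <- function(name, expr) pipelineStage(name, expr, log)$value

  truth <- NULL
  geomCfg <- config$geometry
  if (!is.null(config$phantom)) {
    ph <- config$phantom
    spec <- st("phantom", phantomSpec(
      ventilationState = ph$ventilation_state %||% "high",
      muDTrue = ph$mu_d_true %||% 4.0,
      deltaTrue = ph$delta_true %||% -0.05,
      bhFraction = ph$bh_fraction %||% 0.10,
      fluxRef = ph$flux_ref %||% 1e4,
      visibilityRef = ph$visibility_ref %||% 0.365,
      textureSD = ph$texture_sd %||% 30,
      bronchus = isTRUE(ph$bronchus),
      seed = config$seed))
    geom <- st("geometry", if (is.null(geomCfg)) defaultGeometry()
               else geometryFromConfig(geomCfg))
    gen <- st("phantom", generatePhantomCT(spec))
    ct <- gen$ct
    truth <- gen$truth
    rad <- st("phantom", generatePhantomRadiographs(
      truth, geom, spec, noise = isTRUE(ph$noise)))
    calRecords <- st("calibration", generateCalibrationStack(
      geometry = geom, spec = spec))
    presetDefault <- stateToPreset(spec@ventilationState)
  } else {
    inp <- config$inputs
    ct <- st("input", readVolume(inp$ct))
    geom <- st("geometry", if (is.null(geomCfg))
      stop("an explicit geometry block is required for file inputs")
      else geometryFromConfig(geomCfg))
    rad <- st("input", radiographSet(
      tMap = mapValues(readMap(inp$t_map)),
      nuMap = mapValues(readMap(inp$nu_map)),
      flatIntensity = inp$flat_intensity %||% 1e4,
      flatVisibility = inp$flat_visibility %||% 0.365))
    calRecords <- st("calibration", {
      if (is.null(inp$calibration))
        stop("beam-hardening correction requires a calibration file")
      readCalibrationRecords(inp$calibration)
    })
    presetDefault <- "inspiration"
  }

  thr <- st("segmentation", {
    segCfg <- config$segmentation
    if (!is.null(segCfg$thresholds))
      segmentationThresholds(lLow = segCfg$thresholds[1],
                             lHigh = segCfg$thresholds[2])
    else segmentationThresholds(segCfg$preset %||% presetDefault)
  })
  seg <- st("segmentation", segmentLung(ct, thr))
  vol <- lungVolume(seg)
  M <- st("masking", maskAttenuation(seg, huToRelativeAttenuation(ct)))
  dLung <- st("projection", forwardProject(seg, geom))
  dH2O <- st("projection", forwardProject(M, geom))
  cal <- st("calibration", buildCalibration(calRecords))
  rad <- st("correction", correctBeamHardening(rad, cal))

  thrMM <- config$regression$threshold_mm %||% 3
  mask <- regressionMask(dLung, thrMM)
  if (sum(mask) < 2L)
    stop("pipeline stage 'regression' failed: no lung pixels above threshold")
  w <- st("regression", noiseWeights(rad, mask))
  y <- -log(darkField(rad))
  fitL <- st("regression", weightedLinearFit(dLung, y, w, mask))
  fitH <- st("regression", weightedLinearFit(dH2O, y, w, mask))

  spCfg <- config$spectral
  spectrum <- st("spectral", simulateDetectedSpectrum(
    kv = spCfg$kv %||% 60,
    filtration = unlist(spCfg$filtration) %||% c(Al = 2.5),
    gratingFilter = if (is.null(spCfg$grating_filter)) c(Si = 1.5)
    else unlist(spCfg$grating_filter)))
  mu <- st("spectral", effectiveMuWater(spectrum))

  ns <- normalizedScatter(fitSlope(fitH), mu)
  Tm <- stats::median(transmittance(rad)[mask])
  Dm <- stats::median(darkField(rad)[mask])
  nr <- shotNoiseRatio(Tm, min(Dm, 1), flatVisibility(rad)[1])
  cnr <- cnrRatio(ns, nr)
  fMap <- st("noise_cnr", lungAttenuationFraction(
    dH2O, log(transmittance(rad)), mu))

  summary <- data.frame(
    x_kind = c("d_lung", "d_h2o"),
    slope_1_m = c(fitSlope(fitL), fitSlope(fitH)),
    intercept = c(fitIntercept(fitL), fitIntercept(fitH)),
    r_squared = c(fitRSquared(fitL), fitRSquared(fitH)),
    n_pixels = c(fitL@nPixels, fitH@nPixels),
    lung_volume_l = vol,
    mu_eff_1_m = muEff(mu),
    normalized_scatter = c(NA, ns),
    noise_ratio = nr,
    cnr_ratio = c(NA, cnr@cnrRatio))

  if (!is.null(outDir)) {
    st("output", {
      writeSeededCsv(summary, file.path(outDir, "summary.csv"), config$seed)
      writeMap(dLung, file.path(outDir, "d_lung.tif"))
      writeMap(dH2O, file.path(outDir, "d_h2o.tif"))
      writeMap(-log(darkField(rad)), file.path(outDir, "ln_d.tif"),
               pitch = geom@pixelPitch)
      writeMap(fMap, file.path(outDir, "f_map.tif"),
               pitch = geom@pixelPitch)
      writeHistogram2d(dLung@values[mask], y[mask],
                       file.path(outDir, "hist2d_d_lung.csv"), config$seed)
      invisible(NULL)
    })
  }
  list(fitDLung = fitL, fitDH2O = fitH, lungVolume = vol, muEff = mu,
       normalizedScatter = ns, noiseRatio = nr, cnr = cnr,
       dLung = dLung, dH2O = dH2O, fMap = fMap, radiographs = rad,
       segmentation = seg, summary = summary, truth = truth,
       geometry = geom, mask = mask, weights = w)
}

geometryFromConfig <- function(g) {
  projectionGeometry(
    sourcePosition = unlist(g$source_position),
    detectorOrigin = unlist(g$detector_origin),
    detectorAxes = cbind(unlist(g$detector_axes[[1]]),
                         unlist(g$detector_axes[[2]])),
    pixelPitch = g$pixel_pitch,
    detectorShape = unlist(g$detector_shape),
    volumeRotation = if (is.null(g$volume_rotation)) diag(3)
    else matrix(unlist(g$volume_rotation), 3, 3, byrow = TRUE),
    volumeTranslation = unlist(g$volume_translation %||% c(0, 0, 0)))
}

writeSeededCsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# seed: %d\n", seed), file = con)
  write.csv(format(df, digits = 10), con, row.names = FALSE)
  invisible(path)
}

# plain rectangular 2-D histogram export of the regression scatter
writeHistogram2d <- function(x, y, path, seed, nbins = 40) {
  bx <- seq(min(x), max(x), length.out = nbins + 1)
  by <- seq(min(y), max(y), length.out = nbins + 1)
  ix <- pmin(findInterval(x, bx, rightmost.closed = TRUE), nbins)
  iy <- pmin(findInterval(y, by, rightmost.closed = TRUE), nbins)
  counts <- table(factor(ix, levels = 1:nbins),
                  factor(iy, levels = 1:nbins))
  df <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(df) <- c("x_bin", "y_bin", "count")
  writeSeededCsv(df, path, seed)
}

#' Read calibration records from CSV
#'
#' Long-format CSV with columns \code{height_mm}, \code{column}, \code{t},
#' \code{nu}: one y-averaged node per height and detector column (rows are
#' broadcast to single-row maps).
#'
#' @param path CSV file.
#' @return records list for \code{\link{buildCalibration}}.
#' @export
readCalibrationRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, comment.char = "#")
  hs <- sort(unique(df$height_mm))
  cols <- sort(unique(df$column))
  tCal <- nuCal <- vector("list", length(hs))
  for (k in seq_along(hs)) {
    sub <- df[df$height_mm == hs[k], ]
    sub <- sub[order(sub$column), ]
    tCal[[k]] <- matrix(sub$t, nrow = length(cols))
    nuCal[[k]] <- matrix(sub$nu, nrow = length(cols))
  }
  list(heights = hs, tCal = tCal, nuCal = nuCal)
}

#' Write calibration records to CSV
#'
#' @param records list with heights, tCal, nuCal (per-height matrices).
#' @param path output CSV.
#' @param seed seed recorded in the header comment.
#' @return the path, invisibly.
#' @export
writeCalibrationRecords <- function(records, path, seed = 0L) {
  rows <- do.call(rbind, lapply(seq_along(records$heights), function(k) {
    data.frame(height_mm = records$heights[k],
               column = seq_len(nrow(records$tCal[[k]])),
               t = rowMeans(records$tCal[[k]]),
               nu = rowMeans(records$nuCal[[k]]))
  }))
  writeSeededCsv(rows, path, seed)
  invisible(path)
}
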