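# Generics, accessors and show methods.

#' Voxel size of a grid object
#' @param x a \linkS4class{VoxelGrid} derivative.
#' @return numeric(3), mm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)

#' Grid origin (first voxel center)
#' @param x a \linkS4class{VoxelGrid} derivative.
#' @return numeric(3), mm.
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' Voxel data array
#' @param x a \linkS4class{CTVolume}, \linkS4class{BinaryVolume} or
#'   \linkS4class{AttenuationVolume}.
#' @return the 3-D data array (HU, 0/1, or relative attenuation).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname voxelData
#' @export
setMethod("voxelData", "CTVolume", function(x) x@hu)
#' @rdname voxelData
#' @export
setMethod("voxelData", "BinaryVolume", function(x) x@s)
#' @rdname voxelData
#' @export
setMethod("voxelData", "AttenuationVolume", function(x) x@m)

#' Pixel values of a projection map
#' @param x a \linkS4class{ProjectionMap}.
#' @return numeric matrix in mm.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname mapValues
#' @export
setMethod("mapValues", "ProjectionMap", function(x) x@values)

#' Detector pixel pitch
#' @param x a \linkS4class{ProjectionMap}.
#' @return numeric(1), mm.
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))
#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "ProjectionMap", function(x) x@pixelPitch)

#' Radiograph component maps
#'
#' Accessors for the per-pixel maps of a \linkS4class{RadiographSet}:
#' transmittance, visibility reduction, corrected dark-field signal (NULL
#' before \code{\link{correctBeamHardening}}), and the flat-field intensity
#' and visibility maps.
#'
#' @param x a \linkS4class{RadiographSet}.
#' @return a numeric matrix (or NULL for an unfilled dark-field map).
#' @name radiograph-accessors
NULL

#' @rdname radiograph-accessors
#' @export
setGeneric("transmittance", function(x) standardGeneric("transmittance"))
#' @rdname radiograph-accessors
#' @export
setMethod("transmittance", "RadiographSet", function(x) x@tMap)
#' @rdname radiograph-accessors
#' @export
setGeneric("visibilityReduction",
           function(x) standardGeneric("visibilityReduction"))
#' @rdname radiograph-accessors
#' @export
setMethod("visibilityReduction", "RadiographSet", function(x) x@nuMap)
#' @rdname radiograph-accessors
#' @export
setGeneric("darkField", function(x) standardGeneric("darkField"))
#' @rdname radiograph-accessors
#' @export
setMethod("darkField", "RadiographSet", function(x) x@dMap)
#' @rdname radiograph-accessors
#' @export
setGeneric("flatIntensity", function(x) standardGeneric("flatIntensity"))
#' @rdname radiograph-accessors
#' @export
setMethod("flatIntensity", "RadiographSet", function(x) x@flatIntensity)
#' @rdname radiograph-accessors
#' @export
setGeneric("flatVisibility", function(x) standardGeneric("flatVisibility"))
#' @rdname radiograph-accessors
#' @export
setMethod("flatVisibility", "RadiographSet", function(x) x@flatVisibility)

#' Regression coefficients
#'
#' Accessors for \linkS4class{RegressionFit} (slope in 1/m, dimensionless
#' intercept, weighted R-squared) and \linkS4class{PowerLawFit} (prefactor
#' and exponent of y = a V^b).
#'
#' @param x a fit object.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("fitSlope", function(x) standardGeneric("fitSlope"))
#' @rdname fit-accessors
#' @export
setMethod("fitSlope", "RegressionFit", function(x) x@slope)
#' @rdname fit-accessors
#' @export
setGeneric("fitIntercept", function(x) standardGeneric("fitIntercept"))
#' @rdname fit-accessors
#' @export
setMethod("fitIntercept", "RegressionFit", function(x) x@intercept)
#' @rdname fit-accessors
#' @export
setGeneric("fitRSquared", function(x) standardGeneric("fitRSquared"))
#' @rdname fit-accessors
#' @export
setMethod("fitRSquared", "RegressionFit", function(x) x@rSquared)
#' @rdname fit-accessors
#' @export
setGeneric("powerLawExponent", function(x) standardGeneric("powerLawExponent"))
#' @rdname fit-accessors
#' @export
setMethod("powerLawExponent", "PowerLawFit", function(x) x@b)
#' @rdname fit-accessors
#' @export
setGeneric("powerLawPrefactor",
           function(x) standardGeneric("powerLawPrefactor"))
#' @rdname fit-accessors
#' @export
setMethod("powerLawPrefactor", "PowerLawFit", function(x) x@a)

#' Effective attenuation coefficient value
#' @param x an \linkS4class{EffectiveMu}.
#' @return numeric(1), 1/m.
#' @export
setGeneric("muEff", function(x) standardGeneric("muEff"))
#' @rdname muEff
#' @export
setMethod("muEff", "EffectiveMu", function(x) x@muEff)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@hu)
  cat(sprintf("CTVolume: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3]))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(object@hu), max(object@hu)))
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@s)
  cat(sprintf("BinaryVolume: %d x %d x %d voxels, %d set (%.1f%%)\n",
              d[1], d[2], d[3], sum(object@s),
              100 * mean(object@s)))
})

setMethod("show", "AttenuationVolume", function(object) {
  d <- dim(object@m)
  cat(sprintf(
    "AttenuationVolume: %d x %d x %d voxels, mu/mu_H2O range [%.3f, %.3f]\n",
    d[1], d[2], d[3], min(object@m), max(object@m)))
})

setMethod("show", "ProjectionMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProjectionMap (%s): %d x %d px @ %.3g mm, range [%.2f, %.2f] mm\n",
              object@kind, d[1], d[2], object@pixelPitch,
              min(object@values), max(object@values)))
})

setMethod("show", "RadiographSet", function(object) {
  d <- dim(object@tMap)
  cat(sprintf("RadiographSet: %d x %d px, -lnT range [%.2f, %.2f]%s\n",
              d[1], d[2], -log(max(object@tMap)), -log(min(object@tMap)),
              if (is.null(object@dMap)) ", uncorrected"
              else sprintf(", -lnD range [%.2f, %.2f]",
                           -log(max(object@dMap)), -log(min(object@dMap)))))
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf(
    "RegressionFit vs %s: slope %.4g 1/m (SE %.2g), intercept %.4g (SE %.2g)\n",
    object@xKind, object@slope, object@slopeSE, object@intercept,
    object@interceptSE))
  cat(sprintf("  weighted R^2 = %.4f over %d pixels\n", object@rSquared,
              object@nPixels))
})

setMethod("show", "EffectiveMu", function(object) {
  cat(sprintf(
    "EffectiveMu: %.4g 1/m (R^2 = %.6f, heights up to %g mm, max |resid| %.2g)\n",
    object@muEff, object@rSquared, object@maxHeight, object@maxResidual))
})

setMethod("show", "CnrSummary", function(object) {
  cat(sprintf(
    "CnrSummary: normalized scatter %.3f / noise ratio %.3f = CNR ratio %.4f\n",
    object@normalizedScatter, object@noiseRatio, object@cnrRatio))
})

setMethod("show", "SpectrumModel", function(object) {
  cat(sprintf("SpectrumModel: %g kV tungsten spectrum, %d bins%s\n",
              object@kv, length(object@energyGrid),
              if (object@energyIntegrating) ", energy-integrating" else ""))
  if (length(object@filtration))
    cat("  filtration:",
        paste(sprintf("%s %g mm", names(object@filtration),
                      object@filtration), collapse = ", "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: '%s' ventilation, lung HU %g, mu_d %g 1/m, Delta %g\n",
    object@ventilationState, object@lungMeanHU, object@muDTrue,
    object@deltaTrue))
  cat(sprintf("  bh fraction %.3g, flux %g ph/px, V_r %.3f, seed %d\n",
              object@bhFraction, object@fluxRef, object@visibilityRef,
              object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: lung volume %.3f l, Delta %g, bh fraction %g\n",
              object@lungVolumeTrue, object@deltaTrue, object@bhFraction))
})
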