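# File I/O: NIfTI volumes, 32-bit float TIFF maps, YAML configuration.
#
# Maps are written as uncompressed single-strip 32-bit IEEE float TIFF with
# the pixel pitch in the XResolution/YResolution tags (ResolutionUnit cm).
# The writer/reader pair is implemented here because general-purpose TIFF
# bindings in R only define behaviour for samples in [0, 1], while these
# maps carry physical values (mm, log signals) and NaN.

#' Read a CT volume from NIfTI
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return a \linkS4class{CTVolume} with voxel sizes from the header.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  ctVolume(array(as.vector(img), dim(img)), voxelSize = vox)
}

#' Write a CT volume to NIfTI
#'
#' @param ct a \linkS4class{CTVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(ct, path) {
  stopifnot(is(ct, "CTVolume"))
  img <- RNifti::asNifti(ct@hu)
  RNifti::pixdim(img) <- ct@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- minimal 32-bit float TIFF ------------------------------------------

writeTiffTag <- function(con, tag, type, count, value) {
  writeBin(as.integer(c(tag, type)), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
    writeBin(as.integer(c(value, 0L)), con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a map as 32-bit float TIFF
#'
#' Uncompressed IEEE-float TIFF (little endian, single strip, one sample
#' per pixel) with the pixel pitch stored in the resolution tags
#' (pixels per cm). Values, including NaN, are stored as-is at float32
#' precision. The first matrix index runs along a TIFF row.
#'
#' @param map a \linkS4class{ProjectionMap} or numeric matrix.
#' @param path output path.
#' @param pitch pixel pitch in mm (taken from a ProjectionMap input).
#' @return the path, invisibly.
#' @export
writeMap <- function(map, path, pitch = 1) {
  if (is(map, "ProjectionMap")) {
    pitch <- map@pixelPitch
    map <- map@values
  }
  if (!is.matrix(map)) stop("map must be a matrix or ProjectionMap")
  w <- nrow(map)
  h <- ncol(map)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")        # IFD offset
  nTags <- 13L
  ifdSize <- 2L + nTags * 12L + 4L
  oRes <- 8L + ifdSize                                   # two RATIONALs
  oData <- oRes + 16L
  writeBin(nTags, con, size = 2, endian = "little")
  writeTiffTag(con, 256L, 4L, 1L, w)                     # ImageWidth
  writeTiffTag(con, 257L, 4L, 1L, h)                     # ImageLength
  writeTiffTag(con, 258L, 3L, 1L, 32L)                   # BitsPerSample
  writeTiffTag(con, 259L, 3L, 1L, 1L)                    # no compression
  writeTiffTag(con, 262L, 3L, 1L, 1L)                    # BlackIsZero
  writeTiffTag(con, 273L, 4L, 1L, oData)                 # StripOffsets
  writeTiffTag(con, 277L, 3L, 1L, 1L)                    # SamplesPerPixel
  writeTiffTag(con, 278L, 4L, 1L, h)                     # RowsPerStrip
  writeTiffTag(con, 279L, 4L, 1L, 4L * w * h)            # StripByteCounts
  writeTiffTag(con, 282L, 5L, 1L, oRes)                  # XResolution
  writeTiffTag(con, 283L, 5L, 1L, oRes + 8L)             # YResolution
  writeTiffTag(con, 296L, 3L, 1L, 3L)                    # unit: cm
  writeTiffTag(con, 339L, 3L, 1L, 3L)                    # IEEE float
  writeBin(0L, con, size = 4, endian = "little")         # no next IFD
  den <- as.integer(round(1e6 * pitch))      # pixels per cm = 1e7 / den
  writeBin(c(10000000L, den, 10000000L, den), con, size = 4,
           endian = "little")
  writeBin(as.numeric(map), con, size = 4, endian = "little")
  invisible(path)
}

readTiffValue <- function(con, type, count, endian) {
  # reads the 4-byte value field, dereferencing an offset where needed
  if (type == 3L && count == 1L) {
    v <- readBin(con, "integer", 2, size = 2, signed = FALSE,
                 endian = endian)[1]
    return(v)
  }
  if (type %in% c(4L, 3L) && count == 1L && type == 4L)
    return(readBin(con, "integer", 1, size = 4, endian = endian))
  off <- readBin(con, "integer", 1, size = 4, endian = endian)
  pos <- seek(con)
  seek(con, off)
  v <- if (type == 5L) {
    r <- readBin(con, "integer", 2 * count, size = 4, endian = endian)
    r[seq(1, 2 * count, 2)] / r[seq(2, 2 * count, 2)]
  } else if (type == 3L) {
    readBin(con, "integer", count, size = 2, signed = FALSE, endian = endian)
  } else {
    readBin(con, "integer", count, size = 4, endian = endian)
  }
  seek(con, pos)
  v
}

#' Read a 32-bit float TIFF map
#'
#' Reads maps written by \code{\link{writeMap}} (and other uncompressed
#' single-sample 32-bit float TIFFs), restoring values bit-exactly and the
#' pixel pitch from the resolution tags.
#'
#' @param path TIFF file.
#' @param kind map kind for the returned object ("generic", "d_lung" or
#'   "d_h2o").
#' @return a \linkS4class{ProjectionMap}.
#' @export
readMap <- function(path, kind = "generic") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file: ", path)
  fortytwo <- readBin(con, "integer", 1, size = 2, endian = endian)
  if (fortytwo != 42L) stop("malformed TIFF header: ", path)
  seek(con, readBin(con, "integer", 1, size = 4, endian = endian))
  n <- readBin(con, "integer", 1, size = 2, endian = endian)
  tags <- list()
  for (i in seq_len(n)) {
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                   endian = endian)
    type <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                    endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    tags[[as.character(tag)]] <- readTiffValue(con, type, count, endian)
  }
  need <- function(t, default = NULL) {
    v <- tags[[as.character(t)]]
    if (is.null(v)) {
      if (is.null(default)) stop("missing TIFF tag ", t, " in ", path)
      default
    } else v
  }
  if (need(339, 1L)[1] != 3L || need(258)[1] != 32L)
    stop("unsupported TIFF sample format (need 32-bit float): ", path)
  if (need(259, 1L) != 1L) stop("unsupported TIFF compression: ", path)
  w <- need(256)
  h <- need(257)
  offs <- need(273)
  counts <- need(279, 4L * w * h)
  vals <- numeric(0)
  for (k in seq_along(offs)) {
    seek(con, offs[k])
    vals <- c(vals, readBin(con, "numeric", counts[k] / 4L, size = 4,
                            endian = endian))
  }
  pitch <- 1
  if (!is.null(tags[["282"]])) {
    unit <- need(296, 2L)
    perUnit <- tags[["282"]]
    mmPerUnit <- if (unit == 3L) 10 else if (unit == 2L) 25.4 else 10
    pitch <- mmPerUnit / perUnit
  }
  new("ProjectionMap", values = matrix(vals, w, h), kind = kind,
      pixelPitch = pitch)
}

# --- YAML configuration --------------------------------------------------

#' Read and validate a pipeline configuration
#'
#' YAML configuration for \code{\link{runPipeline}}. Units: mm for geometry
#' and maps, HU for thresholds, 1/m for coefficients. Either a
#' \code{phantom} block (ventilation_state, noise, and optional overrides of
#' the \code{\link{phantomSpec}} arguments in snake_case) or an
#' \code{inputs} block (paths to a NIfTI CT, T and nu TIFF maps, flat-field
#' statistics and a calibration CSV) must be present. Optional blocks:
#' \code{segmentation} (preset or thresholds), \code{geometry} (see
#' \code{\link{projectionGeometry}}; phantom runs default to
#' \code{\link{defaultGeometry}}), \code{regression} (threshold_mm),
#' \code{spectral} (kv, filtration, grating_filter), \code{output_dir},
#' \code{seed}.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
  if (is.null(cfg$phantom) && is.null(cfg$inputs))
    stop("config must contain a 'phantom' or an 'inputs' block")
  if (!is.null(cfg$inputs)) {
    for (f in c("ct", "t_map", "nu_map"))
      if (is.null(cfg$inputs[[f]]) || !file.exists(cfg$inputs[[f]]))
        stop("config inputs: missing file for '", f, "'")
  }
  if (!is.null(cfg$segmentation$thresholds)) {
    thr <- cfg$segmentation$thresholds
    if (length(thr) != 2L || thr[1] >= thr[2])
      stop("config segmentation thresholds must be [lLow, lHigh], lLow < lHigh")
  }
  if (!is.null(cfg$regression$threshold_mm) &&
      cfg$regression$threshold_mm < 0)
    stop("config regression threshold must be >= 0")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}
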