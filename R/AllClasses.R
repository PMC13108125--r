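## Central S4 data structures. Images are channels x height x width arrays in
## [0, 1]; normalized coordinates put (0, 0) at the image center with x and y
## each spanning [-1, 1] (x rightward with columns, y downward with rows, pixel
## centers at ((2c + 1)/W - 1, (2r + 1)/H - 1) for 0-based row r, column c).

#' Foveation (log-polar grid) configuration
#'
#' Holds every parameter of the retinotopic sampling grid: the azimuth and
#' eccentricity resolutions, the inner and outer log2-radii of the sampled
#' annulus, the fixation point in normalized coordinates, and the fill value
#' used for samples falling outside the source raster. The defaults give the
#' standard 224 x 224 grid spanning eccentricities from 2^-5 to 1 (the outer
#' ring tangent to the image box) fixating the image center.
#'
#' Radii are geometrically spaced: log2 of the eccentricity is uniform on
#' `[log2RMin, log2RMax]`, so that uniform zooms about the fixation point
#' become row shifts of the log-polar raster (and rotations become column
#' shifts).
#'
#' @slot nTheta integer, number of azimuth samples (>= 2).
#' @slot nRho integer, number of eccentricity samples (>= 2).
#' @slot log2RMin,log2RMax inner/outer log2-radius in normalized units,
#'   `log2RMin < log2RMax`.
#' @slot fixation numeric(2), fixation point (x0, y0), each in [-1, 1].
#' @slot fillValue value for out-of-frame samples.
#' @export
setClass("FoveationConfig",
  representation(nTheta = "integer", nRho = "integer",
                 log2RMin = "numeric", log2RMax = "numeric",
                 fixation = "numeric", fillValue = "numeric"),
  validity = function(object) {
    if (length(object@nTheta) != 1L || is.na(object@nTheta) || object@nTheta < 2L)
      return("nTheta: must be a single integer >= 2")
    if (length(object@nRho) != 1L || is.na(object@nRho) || object@nRho < 2L)
      return("nRho: must be a single integer >= 2")
    if (!is.finite(object@log2RMin)) return("log2RMin: must be finite")
    if (!is.finite(object@log2RMax)) return("log2RMax: must be finite")
    if (object@log2RMin >= object@log2RMax)
      return("log2RMin: must be strictly smaller than log2RMax")
    if (length(object@fixation) != 2L || any(!is.finite(object@fixation)))
      return("fixation: must be two finite numbers")
    if (any(abs(object@fixation) > 1))
      return("fixation: components must lie in [-1, 1]")
    if (!is.finite(object@fillValue)) return("fillValue: must be finite")
    TRUE
  })

#' @describeIn FoveationConfig-class Constructor.
#' @param nTheta,nRho,log2RMin,log2RMax,fixation,fillValue see slots.
#' @return a validated `FoveationConfig`.
#' @examples
#' cfg <- FoveationConfig()           # the standard 224 x 224 grid
#' FoveationConfig(nTheta = 64, nRho = 64, fixation = c(0.25, 0))
#' @export
FoveationConfig <- function(nTheta = 224L, nRho = 224L,
                            log2RMin = -5, log2RMax = 0,
                            fixation = c(0, 0), fillValue = 0) {
  new("FoveationConfig",
      nTheta = as.integer(nTheta), nRho = as.integer(nRho),
      log2RMin = as.numeric(log2RMin), log2RMax = as.numeric(log2RMax),
      fixation = as.numeric(fixation), fillValue = as.numeric(fillValue))
}

#' @export
setMethod("show", "FoveationConfig", function(object) {
  cat(sprintf(
    "FoveationConfig: %d azimuths x %d eccentricities, log2 radius [%g, %g],\n  fixation (%g, %g), fill %g\n",
    object@nTheta, object@nRho, object@log2RMin, object@log2RMax,
    object@fixation[1], object@fixation[2], object@fillValue))
})

#' @rdname FoveationConfig-class
#' @param object,x a `FoveationConfig`.
#' @export
nTheta <- function(x) x@nTheta
#' @rdname FoveationConfig-class
#' @export
nRho <- function(x) x@nRho
#' @rdname FoveationConfig-class
#' @export
fixation <- function(x) x@fixation
#' @rdname FoveationConfig-class
#' @export
fillValue <- function(x) x@fillValue

#' Cartesian image raster
#'
#' A channels x height x width numeric array (values typically in [0, 1])
#' with the normalized coordinate frame described in [FoveationConfig-class].
#' The class extends `array`, so ordinary array indexing and `dim()` work.
#' A matrix input is promoted to a single-channel raster.
#'
#' @param values numeric array (channels x H x W) or matrix (H x W).
#' @return an `ImageRaster`.
#' @examples
#' img <- ImageRaster(matrix(runif(64 * 64), 64, 64))
#' dim(img)
#' @export ImageRaster
#' @exportClass ImageRaster
setClass("ImageRaster", contains = "array",
  validity = function(object) {
    d <- dim(object)
    if (length(d) != 3L) return("values must be a channels x height x width array")
    if (d[1] < 1L) return("channel count must be >= 1")
    if (d[2] < 2L || d[3] < 2L) return("height and width must be >= 2")
    if (any(!is.finite(object@.Data))) return("pixel values must be finite")
    TRUE
  })

ImageRaster <- function(values) {
  if (is.matrix(values)) values <- array(values, c(1L, nrow(values), ncol(values)))
  if (inherits(values, "ImageRaster")) return(values)
  new("ImageRaster", values)
}

#' @export
setMethod("show", "ImageRaster", function(object) {
  d <- dim(object)
  cat(sprintf("ImageRaster: %d channel(s), %d x %d, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(object), max(object)))
})

## internal: accept ImageRaster / array / matrix, return plain c x H x W array
.rasterArray <- function(image) {
  if (inherits(image, "ImageRaster")) return(image@.Data)
  if (is.matrix(image)) return(array(image, c(1L, nrow(image), ncol(image))))
  if (is.array(image) && length(dim(image)) == 3L) return(image)
  stop("expected an ImageRaster, a channels x H x W array, or a matrix",
       call. = FALSE)
}

#' Log-polar sampling grid
#'
#' The Cartesian source location of every (eccentricity, azimuth) sample.
#'
#' @slot coords nRho x nTheta x 2 array of (x, y) source coordinates.
#' @slot rho eccentricities (length nRho, geometric progression).
#' @slot theta azimuths in radians (length nTheta, uniform on [0, 2*pi)).
#' @slot config the generating [FoveationConfig-class].
#' @export
setClass("SamplingGrid",
  representation(coords = "array", rho = "numeric", theta = "numeric",
                 config = "FoveationConfig"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[3] != 2L) return("coords must be nRho x nTheta x 2")
    if (d[1] != object@config@nRho || d[2] != object@config@nTheta)
      return("coords dimensions disagree with config")
    TRUE
  })

#' @export
setMethod("show", "SamplingGrid", function(object) {
  cat(sprintf("SamplingGrid: %d x %d samples, rho in [%g, %g]\n",
              object@config@nRho, object@config@nTheta,
              min(object@rho), max(object@rho)))
})

#' Log-polar (retinotopic) image
#'
#' A channels x nRho x nTheta array: row index = eccentricity ring (fovea at
#' row 1), column index = azimuth. Carries the [FoveationConfig-class] that
#' produced it. Extends `array`.
#'
#' @param values channels x nRho x nTheta array (or nRho x nTheta matrix).
#' @param config the generating `FoveationConfig`.
#' @export LogPolarImage
#' @exportClass LogPolarImage
setClass("LogPolarImage", contains = "array",
  representation(config = "FoveationConfig"),
  validity = function(object) {
    d <- dim(object)
    if (length(d) != 3L) return("values must be channels x nRho x nTheta")
    if (d[2] != object@config@nRho || d[3] != object@config@nTheta)
      return("array shape disagrees with config (nRho, nTheta)")
    if (any(!is.finite(object@.Data))) return("values must be finite")
    TRUE
  })

LogPolarImage <- function(values, config) {
  if (is.matrix(values)) values <- array(values, c(1L, nrow(values), ncol(values)))
  new("LogPolarImage", values, config = config)
}

#' @export
setMethod("show", "LogPolarImage", function(object) {
  d <- dim(object)
  cat(sprintf("LogPolarImage: %d channel(s), %d eccentricities x %d azimuths\n",
              d[1], d[2], d[3]))
})

#' @export
setMethod("mapValues", "LogPolarImage", function(x) x@.Data)

#' Fixation-grid likelihood map
#'
#' Per-fixation likelihood of a cued label over a G x G grid of fixation
#' points, with the crop metadata of every cell. Produced by
#' [likelihoodMap()].
#'
#' @slot values G x G matrix of probabilities in [0, 1]; row = y (downward),
#'   column = x (rightward), matching the fixation grid layout.
#' @slot fixations G x G x 2 array of normalized fixation coordinates.
#' @slot cropRadii G x G matrix of normalized crop radii.
#' @slot label integer label(s) the map is cued to.
#' @slot mode `"cartesian"` or `"retinotopic"`.
#' @export
setClass("LikelihoodMap",
  representation(values = "matrix", fixations = "array",
                 cropRadii = "matrix", label = "integer", mode = "character"),
  validity = function(object) {
    G <- nrow(object@values)
    if (ncol(object@values) != G) return("values must be square (G x G)")
    if (any(object@values < -1e-9) || any(object@values > 1 + 1e-9))
      return("likelihoods must lie in [0, 1]")
    if (!identical(dim(object@fixations), c(G, G, 2L)))
      return("fixations must be G x G x 2")
    if (!identical(dim(object@cropRadii), dim(object@values)))
      return("cropRadii must match values")
    if (!object@mode %in% c("cartesian", "retinotopic"))
      return("mode must be 'cartesian' or 'retinotopic'")
    TRUE
  })

#' @export
setMethod("show", "LikelihoodMap", function(object) {
  cat(sprintf(
    "LikelihoodMap: %d x %d fixations, label %s, mode %s, peak %.3f\n",
    nrow(object@values), ncol(object@values),
    paste(object@label, collapse = ","), object@mode, max(object@values)))
})

#' @export
setMethod("mapValues", "LikelihoodMap", function(x) x@values)

#' Recentered aggregate likelihood maps
#'
#' The per-cell mean of peak-recentered likelihood maps on a
#' (2G-1) x (2G-1) canvas. Cells never covered by any map are undefined;
#' `values` holds `NA` there and `counts` the number of contributing maps.
#'
#' @slot values (2G-1) x (2G-1) mean map with NA at undefined cells.
#' @slot counts matching matrix of contributing-map counts.
#' @export
setClass("AggregateMaps",
  representation(values = "matrix", counts = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@values), dim(object@counts)))
      return("values and counts must have the same shape")
    if (nrow(object@values) != ncol(object@values) ||
        nrow(object@values) %% 2L != 1L)
      return("canvas must be square with odd side (2G-1)")
    if (any(is.na(object@values) != (object@counts == 0L)))
      return("NA cells must be exactly the zero-count cells")
    TRUE
  })

#' @export
setMethod("show", "AggregateMaps", function(object) {
  cat(sprintf("AggregateMaps: %d x %d canvas, %d undefined cell(s), center %.3f\n",
              nrow(object@values), ncol(object@values),
              sum(object@counts == 0L),
              object@values[(nrow(object@values) + 1L) / 2L,
                            (ncol(object@values) + 1L) / 2L]))
})

#' @export
setMethod("mapValues", "AggregateMaps", function(x) x@values)

#' Localization ground truth
#'
#' Either a normalized bounding box or a keypoint-derived Gaussian heat map,
#' reduced to a G x G grid with a binary mask for scoring.
#'
#' @slot bbox numeric(4) `(xMin, yMin, xMax, yMax)` in normalized coordinates,
#'   or NA when keypoint-derived.
#' @slot heatmap G x G values in [0, 1] (peak 1 for keypoint maps).
#' @slot mask G x G logical mask used by the localization scores.
#' @slot source `"box"` or `"keypoints"`.
#' @export
setClass("GroundTruth",
  representation(bbox = "numeric", heatmap = "matrix", mask = "matrix",
                 source = "character"),
  validity = function(object) {
    if (length(object@bbox) != 4L) return("bbox must have four components")
    if (!all(is.na(object@bbox))) {
      if (any(!is.finite(object@bbox))) return("bbox must be finite")
      if (object@bbox[1] >= object@bbox[3] || object@bbox[2] >= object@bbox[4])
        return("bbox must satisfy xMin < xMax and yMin < yMax")
    }
    if (!identical(dim(object@heatmap), dim(object@mask)))
      return("heatmap and mask must have the same shape")
    if (max(object@heatmap) > 1 + 1e-9) return("heat map peak must be <= 1")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!any(object@mask)) return("binary mask must be non-empty")
    if (!object@source %in% c("box", "keypoints"))
      return("source must be 'box' or 'keypoints'")
    TRUE
  })

#' @export
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth (%s): %d x %d grid, %d cell(s) in mask\n",
              object@source, nrow(object@mask), ncol(object@mask),
              sum(object@mask)))
})

#' Worst-case geometric attack result
#'
#' @slot kind `"rotation"`, `"zoom"` or `"translation"`.
#' @slot worstParam parameter value maximizing the loss (degrees, zoom
#'   factor, or normalized fixation point).
#' @slot worstLoss cross-entropy at the worst parameter.
#' @slot losses full loss vector over the search grid.
#' @slot grid the searched parameter grid (matrix for translation).
#' @slot predictedLabel arg-max label at the worst parameter (1-based).
#' @slot trueLabel the ground-truth label.
#' @slot correct whether predictedLabel == trueLabel.
#' @export
setClass("AttackResult",
  representation(kind = "character", worstParam = "numeric",
                 worstLoss = "numeric", losses = "numeric", grid = "matrix",
                 predictedLabel = "integer", trueLabel = "integer",
                 correct = "logical"),
  validity = function(object) {
    if (!object@kind %in% c("rotation", "zoom", "translation"))
      return("kind must be rotation, zoom or translation")
    if (object@worstLoss < max(object@losses) - 1e-12)
      return("worstLoss must be the maximum over the grid")
    TRUE
  })

#' @export
setMethod("show", "AttackResult", function(object) {
  cat(sprintf(
    "AttackResult (%s): worst parameter %s, loss %.4f, predicted %d vs true %d (%s)\n",
    object@kind, paste(signif(object@worstParam, 4), collapse = ","),
    object@worstLoss, object@predictedLabel, object@trueLabel,
    if (object@correct) "correct" else "wrong"))
})

#' Accuracy sweep curve
#'
#' Mean top-1 accuracy over a dataset at each value of a 1-D parameter grid.
#'
#' @slot kind transform kind.
#' @slot grid strictly ordered parameter values.
#' @slot accuracy accuracies in [0, 1], one per grid value.
#' @export
setClass("SweepCurve",
  representation(kind = "character", grid = "numeric", accuracy = "numeric"),
  validity = function(object) {
    if (length(object@grid) != length(object@accuracy))
      return("grid and accuracy must have equal length")
    if (length(object@grid) > 1L && any(diff(object@grid) <= 0))
      return("grid must be strictly increasing")
    if (any(object@accuracy < 0 | object@accuracy > 1))
      return("accuracies must lie in [0, 1]")
    TRUE
  })

#' @export
setMethod("show", "SweepCurve", function(object) {
  cat(sprintf("SweepCurve (%s): %d grid points, accuracy %.3f .. %.3f\n",
              object@kind, length(object@grid),
              min(object@accuracy), max(object@accuracy)))
})

#' Synthetic fixture dataset
#'
#' A set of generated scenes with exact annotations, in either the
#' `"regular"` variant (objects anywhere in the frame) or the `"focus"`
#' variant (smallest-square bounding-box crops recentred on the object).
#'
#' @slot images list of `ImageRaster`.
#' @slot labels integer class labels (1-based).
#' @slot classNames character class names.
#' @slot bboxes n x 4 matrix of normalized boxes (xMin, yMin, xMax, yMax).
#' @slot keypoints list of k x 2 matrices of normalized keypoints.
#' @slot centers n x 2 matrix of object centers.
#' @slot scales numeric object scales (half-size, normalized units).
#' @slot variant `"regular"` or `"focus"`.
#' @export
setClass("FixtureDataset",
  representation(images = "list", labels = "integer", classNames = "character",
                 bboxes = "matrix", keypoints = "list", centers = "matrix",
                 scales = "numeric", variant = "character"),
  validity = function(object) {
    n <- length(object@images)
    if (length(object@labels) != n || nrow(object@bboxes) != n ||
        length(object@keypoints) != n || nrow(object@centers) != n ||
        length(object@scales) != n)
      return("annotation lengths must match the number of images")
    if (!object@variant %in% c("regular", "focus"))
      return("variant must be 'regular' or 'focus'")
    if (any(object@labels < 1L | object@labels > length(object@classNames)))
      return("labels out of range of classNames")
    TRUE
  })

#' @export
setMethod("show", "FixtureDataset", function(object) {
  cat(sprintf("FixtureDataset (%s): %d scenes, %d classes (%s)\n",
              object@variant, length(object@images),
              length(object@classNames),
              paste(object@classNames, collapse = ", ")))
})

#' @describeIn FixtureDataset-class Number of scenes.
#' @param x a `FixtureDataset`.
#' @export
setMethod("length", "FixtureDataset", function(x) length(x@images))
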