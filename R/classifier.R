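## The classifier contract: anything that maps a batch of Cartesian image
## rasters to an N x K matrix of class probabilities can be attacked, swept
## and used to build likelihood maps. Geometric perturbations and fixation
## crops are always applied in image space; a retinotopic classifier performs
## its own foveation as fixed preprocessing (perturb -> foveate -> classify).

#' Virtual parent of all classifiers
#'
#' @slot mode `"cartesian"` or `"retinotopic"`.
#' @slot resolution integer(2) input (height, width).
#' @slot nClasses number of labels K.
#' @export
setClass("Classifier", representation("VIRTUAL",
  mode = "character", resolution = "integer", nClasses = "integer"))

#' @export
setMethod("inputMode", "Classifier", function(object) object@mode)

#' @export
setMethod("inputResolution", "Classifier", function(object) object@resolution)

#' Wrap an R function as a classifier
#'
#' The function receives a list of channels x H x W arrays and must return an
#' N x K probability matrix (or a single length-K vector for N = 1). Useful
#' for oracles and degenerate classifiers in tests (e.g. a rotation-blind
#' classifier returning a constant vector).
#'
#' @param fn the prediction function.
#' @param nClasses number of labels K.
#' @param mode `"cartesian"` or `"retinotopic"` (controls which preprocessing
#'   pipelines callers assume; the function itself always sees Cartesian
#'   rasters).
#' @param resolution input resolution `(height, width)`.
#' @return a `FunctionClassifier`.
#' @examples
#' clf <- FunctionClassifier(function(imgs)
#'   matrix(1 / 4, length(imgs), 4), nClasses = 4)
#' @export FunctionClassifier
#' @exportClass FunctionClassifier
setClass("FunctionClassifier", contains = "Classifier",
         representation(fn = "function"))

FunctionClassifier <- function(fn, nClasses, mode = "cartesian",
                               resolution = c(64L, 64L)) {
  mode <- match.arg(mode, c("cartesian", "retinotopic"))
  new("FunctionClassifier", fn = fn, nClasses = as.integer(nClasses),
      mode = mode, resolution = as.integer(resolution))
}

## normalize a batch argument to a list of plain arrays
.imageBatch <- function(images) {
  if (inherits(images, "ImageRaster") || is.matrix(images) ||
      (is.array(images) && length(dim(images)) == 3L))
    images <- list(images)
  lapply(images, .rasterArray)
}

#' Validate a probability matrix against the classifier contract
#'
#' Checks that every row is non-negative and sums to 1 within 1e-6; errors
#' otherwise. Returns the matrix invisibly so it can be used as a pass-through
#' assertion.
#'
#' @param probs numeric matrix, one row per image.
#' @return `probs`, invisibly.
#' @export
checkProbabilityContract <- function(probs) {
  if (!is.matrix(probs) || !is.numeric(probs))
    stop("classifier output must be a numeric matrix")
  if (any(probs < -1e-9))
    stop("classifier output violates the probability contract: negative entries")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("classifier output violates the probability contract: rows must sum to 1")
  invisible(probs)
}

#' @describeIn FunctionClassifier-class Predict probabilities via the wrapped
#'   function, enforcing the probability contract.
#' @param object a `FunctionClassifier`.
#' @param images list of image rasters (or a single raster).
#' @export
setMethod("predictProbs", "FunctionClassifier", function(object, images) {
  images <- .imageBatch(images)
  p <- object@fn(images)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (ncol(p) != object@nClasses)
    stop("classifier returned ", ncol(p), " columns for ", object@nClasses,
         " classes")
  checkProbabilityContract(p)
  p
})

#' @export
setMethod("show", "Classifier", function(object) {
  cat(sprintf("%s: %s input %d x %d, %d classes\n", class(object),
              object@mode, object@resolution[1], object@resolution[2],
              object@nClasses))
})
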