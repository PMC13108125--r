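#' @import methods
#' @importFrom stats cor rnorm runif sd
NULL

#' Predict class probabilities for a batch of images
#'
#' The single contract every classifier used by the attack and likelihood-map
#' machinery must satisfy: given a list of Cartesian image rasters, return an
#' N x K matrix of class probabilities, each row non-negative and summing to
#' one (within 1e-6). Built-in methods exist for [ToyClassifier] (the trained
#' convolutional harness) and [FunctionClassifier] (an arbitrary R function);
#' user classes can add their own method.
#'
#' @param object a classifier.
#' @param images a list of image rasters (`ImageRaster` or plain
#'   channels x height x width arrays), or a single raster.
#' @return numeric matrix, one row per image, one column per class label.
#' @export
setGeneric("predictProbs", function(object, images) standardGeneric("predictProbs"))

#' Input mode of a classifier
#'
#' Either `"cartesian"` (circular-masked Cartesian input) or `"retinotopic"`
#' (log-polar transformed input). The mode decides which preprocessing the
#' attack and likelihood-map pipelines assume: geometric perturbations are
#' always applied in image space, *before* any foveation.
#'
#' @param object a classifier.
#' @return character scalar.
#' @export
setGeneric("inputMode", function(object) standardGeneric("inputMode"))

#' Input resolution of a classifier
#'
#' @param object a classifier.
#' @return integer vector `c(height, width)`.
#' @export
setGeneric("inputResolution", function(object) standardGeneric("inputResolution"))

#' Extract the numeric values of a map or image object
#'
#' @param x a `LogPolarImage`, `LikelihoodMap` or `AggregateMaps` object.
#' @return a numeric array or matrix.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
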