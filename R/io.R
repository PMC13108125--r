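## File interchange: PNG rasters, portable binary arrays with JSON sidecars
## for log-polar images, and the JSON annotation dialect
## {image, label, bbox, keypoints} shared with the localization metrics.

#' Read an image raster from a PNG file
#'
#' @param path PNG file; gray, gray+alpha, RGB and RGBA are accepted (alpha
#'   is dropped).
#' @return an [ImageRaster] with values in [0, 1].
#' @export
readImageRaster <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (dim(a)[3] %in% c(2L, 4L)) a <- a[, , -dim(a)[3], drop = FALSE]
  ImageRaster(aperm(a, c(3, 1, 2)))
}

#' Write an image raster to a PNG file
#'
#' Values are clamped to [0, 1]; single-channel rasters are written as
#' grayscale.
#'
#' @param image an `ImageRaster`, array, or matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeImageRaster <- function(image, path) {
  arr <- pmin(pmax(.rasterArray(image), 0), 1)
  a <- aperm(arr, c(2, 3, 1))
  if (dim(a)[3] == 1L) a <- a[, , 1]
  png::writePNG(a, path)
  invisible(path)
}

#' Save a log-polar image as a portable binary array
#'
#' Writes the raw values as little-endian doubles and a JSON sidecar
#' (`<path>.json`) carrying the array dimensions and the full
#' [FoveationConfig-class], so the object round-trips across platforms.
#'
#' @param lp a [LogPolarImage-class].
#' @param path output file for the binary values.
#' @return `path`, invisibly.
#' @export
saveLogPolar <- function(lp, path) {
  stopifnot(is(lp, "LogPolarImage"))
  con <- file(path, "wb")
  writeBin(as.vector(lp@.Data), con, size = 8, endian = "little")
  close(con)
  cfg <- lp@config
  meta <- list(dim = dim(lp),
               config = list(nTheta = cfg@nTheta, nRho = cfg@nRho,
                             log2RMin = cfg@log2RMin, log2RMax = cfg@log2RMax,
                             fixation = cfg@fixation,
                             fillValue = cfg@fillValue))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a log-polar image saved by [saveLogPolar()]
#'
#' @param path file written by [saveLogPolar()].
#' @return a [LogPolarImage-class].
#' @export
loadLogPolar <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  cfg <- meta$config
  LogPolarImage(array(v, meta$dim),
                FoveationConfig(nTheta = cfg$nTheta, nRho = cfg$nRho,
                                log2RMin = cfg$log2RMin,
                                log2RMax = cfg$log2RMax,
                                fixation = cfg$fixation,
                                fillValue = cfg$fillValue))
}

#' Write annotations for a fixture dataset as JSON
#'
#' One record per scene: `{image, label, bbox: [x0, y0, x1, y1],
#' keypoints: [[x, y], ...]}` with normalized coordinates.
#'
#' @param data a [FixtureDataset-class].
#' @param path output JSON file.
#' @param imageNames file names to store in the `image` field.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(data, path,
                             imageNames = sprintf("scene%04d.png",
                                                  seq_len(length(data)))) {
  recs <- lapply(seq_len(length(data)), function(i)
    list(image = imageNames[i],
         label = data@classNames[data@labels[i]],
         bbox = data@bboxes[i, ],
         keypoints = lapply(seq_len(nrow(data@keypoints[[i]])), function(k)
           data@keypoints[[i]][k, ])))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotations written by [writeAnnotations()]
#'
#' @param path JSON annotation file.
#' @return list of records with `image`, `label`, `bbox` (numeric(4)) and
#'   `keypoints` (k x 2 matrix).
#' @export
readAnnotations <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    list(image = r$image, label = r$label,
         bbox = as.numeric(unlist(r$bbox)),
         keypoints = do.call(rbind, lapply(r$keypoints, function(k)
           as.numeric(unlist(k))))))
}
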