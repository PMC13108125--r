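## Image-space rotation, zoom and wraparound translation, plus the analytic
## log-polar shift predictions that make equivariance measurable.
##
## Rotation and zoom are implemented by inverse mapping with the shared
## bilinear sampler: each output pixel looks up its source location, so the
## interpolation rule is identical to the forward retinotopic transform.
## Identity parameters (angle 0, factor 1) return the input bit-exactly.

#' Rotate an image about a center
#'
#' Content at angle `theta - angle` (measured from `center`) moves to angle
#' `theta`: under the package's axis convention (y downward) a positive angle
#' rotates content clockwise on screen. Out-of-frame source samples receive
#' `fill`.
#'
#' @param image an `ImageRaster`, array, or matrix.
#' @param angle rotation angle in radians.
#' @param center normalized rotation center.
#' @param fill fill value for exposed regions.
#' @return an [ImageRaster].
#' @export
rotateImage <- function(image, angle, center = c(0, 0), fill = 0) {
  if (!is.numeric(angle) || length(angle) != 1 || !is.finite(angle))
    stop("angle must be a single finite number")
  arr <- .rasterArray(image)
  if (angle == 0) return(ImageRaster(arr))
  d <- dim(arr)
  xy <- .gridXY(d[2], d[3])
  dx <- xy$x - center[1]; dy <- xy$y - center[2]
  ca <- cos(angle); sa <- sin(angle)
  sx <- center[1] + ca * dx + sa * dy     # inverse rotation of the offset
  sy <- center[2] - sa * dx + ca * dy
  v <- .bilinearSample(arr, sx, sy, fill = fill)
  ImageRaster(array(v, d))
}

#' Zoom an image about a center
#'
#' Content at radius `r` from `center` appears at radius `factor * r`:
#' factors above 1 magnify, factors below 1 shrink and expose frame filled
#' with `fill`.
#'
#' @param image an `ImageRaster`, array, or matrix.
#' @param factor positive zoom factor; 1 is the identity.
#' @param center normalized zoom center.
#' @param fill fill value for exposed regions.
#' @return an [ImageRaster].
#' @export
zoomImage <- function(image, factor, center = c(0, 0), fill = 0) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0)
    stop("factor must be a single positive number")
  arr <- .rasterArray(image)
  if (factor == 1) return(ImageRaster(arr))
  d <- dim(arr)
  xy <- .gridXY(d[2], d[3])
  sx <- center[1] + (xy$x - center[1]) / factor
  sy <- center[2] + (xy$y - center[2]) / factor
  v <- .bilinearSample(arr, sx, sy, fill = fill)
  ImageRaster(array(v, d))
}

#' Wraparound (roll) translation
#'
#' Circularly shifts the pixel content by the nearest whole-pixel offset.
#' `shift` is expressed in image widths/heights: `c(0.5, 0)` rolls the
#' content half a frame rightward, `c(1, 0)` is the identity. Quantizing to
#' integer pixels keeps the operation an exact permutation of pixel values
#' (sub-pixel wraparound would blend opposite image edges).
#'
#' @param image an `ImageRaster`, array, or matrix.
#' @param shift numeric(2) `(dx, dy)` in units of the frame size.
#' @return an [ImageRaster].
#' @export
translateRoll <- function(image, shift) {
  if (length(shift) != 2 || any(!is.finite(shift)))
    stop("shift must be two finite numbers")
  arr <- .rasterArray(image)
  d <- dim(arr)
  px <- round(shift[1] * d[3]) %% d[3]
  py <- round(shift[2] * d[2]) %% d[2]
  if (px == 0 && py == 0) return(ImageRaster(arr))
  rows <- ((seq_len(d[2]) - 1 - py) %% d[2]) + 1
  cols <- ((seq_len(d[3]) - 1 - px) %% d[3]) + 1
  ImageRaster(arr[, rows, cols, drop = FALSE])
}

#' Predicted log-polar shift of a rotation or zoom
#'
#' The analytic translation induced in log-polar space by a rotation or a
#' uniform zoom centered on the fixation point: a rotation by `angle` shifts
#' the azimuth axis by `angle * nTheta / (2 * pi)` columns; a zoom by factor
#' `s` shifts the eccentricity axis by
#' `log2(s) * (nRho - 1) / (log2RMax - log2RMin)` rows. No closed-form shift
#' exists for a translation — that failure is exactly what the translation
#' attack and the fixation-map machinery exploit.
#'
#' @param kind `"rotation"` or `"zoom"` (`"translation"` is an error).
#' @param value rotation angle in radians, or zoom factor.
#' @param config a [FoveationConfig-class].
#' @return numeric(2) `(rowShift, colShift)` in grid cells.
#' @examples
#' predictedLogPolarShift("zoom", 2, FoveationConfig())   # 44.6 rows
#' @export
predictedLogPolarShift <- function(kind, value, config) {
  kind <- match.arg(kind, c("rotation", "zoom", "translation"))
  if (kind == "translation")
    stop("translations have no closed-form log-polar shift")
  if (kind == "rotation")
    c(0, value * config@nTheta / (2 * pi))
  else {
    if (value <= 0) stop("zoom factor must be positive")
    c(log2(value) * (config@nRho - 1) / (config@log2RMax - config@log2RMin), 0)
  }
}

## Shift a matrix by a (possibly fractional) offset along one axis with
## linear interpolation. circular = TRUE wraps; otherwise cells whose source
## falls off the matrix are flagged invalid. Returns list(values, valid).
.shiftMatrix <- function(m, offset, axis = c("row", "col"), circular = FALSE) {
  axis <- match.arg(axis)
  if (axis == "col") {
    r <- .shiftMatrix(t(m), offset, "row", circular)
    return(list(values = t(r$values), valid = t(r$valid)))
  }
  n <- nrow(m)
  src <- seq_len(n) - offset               # value at row i comes from i - offset
  if (circular) {
    s0 <- floor(src); w <- src - s0
    i0 <- ((s0 - 1) %% n) + 1
    i1 <- (s0 %% n) + 1
    vals <- m[i0, , drop = FALSE] * (1 - w) + m[i1, , drop = FALSE] * w
    list(values = vals, valid = matrix(TRUE, n, ncol(m)))
  } else {
    s0 <- floor(src); w <- src - s0
    ok <- s0 >= 1 & s0 + 1 <= n
    i0 <- pmin(pmax(s0, 1), n - 1)
    vals <- m[i0, , drop = FALSE] * (1 - w) + m[i0 + 1, , drop = FALSE] * w
    vals[!ok, ] <- NA_real_
    list(values = vals, valid = matrix(ok, n, ncol(m)))
  }
}

#' Log-polar equivariance error of a rotation or zoom
#'
#' Measures how closely the log-polar representation of a transformed image
#' matches the predicted shift of the log-polar representation of the
#' original: rotations should appear as circular column shifts, zooms as row
#' shifts. Returns the Pearson correlation over the jointly valid region.
#' The innermost `excludeRings` rings are excluded by default: the fovea
#' oversamples a handful of source pixels, so interpolation error dominates
#' there without carrying information about the equivariance itself.
#' The outermost `excludeOuter` rings are excluded as well: with the default
#' outer radius the last ring lies exactly on the frame border, where
#' samples are clamped to border pixel centers, and that clamping is
#' frame-aligned rather than transform-equivariant.
#'
#' @param image an `ImageRaster`, array, or matrix (non-constant).
#' @param kind `"rotation"` or `"zoom"`.
#' @param value rotation angle in radians, or zoom factor.
#' @param config a [FoveationConfig-class]; the transform is applied about
#'   its fixation point.
#' @param excludeRings number of innermost rings dropped from the comparison.
#' @param excludeOuter number of outermost rings dropped from the comparison.
#' @return correlation in [-1, 1] (1 means perfect equivariance).
#' @export
equivarianceError <- function(image, kind, value, config, excludeRings = 5L,
                              excludeOuter = 1L) {
  kind <- match.arg(kind, c("rotation", "zoom"))
  arr <- .rasterArray(image)
  shift <- predictedLogPolarShift(kind, value, config)
  transformed <- if (kind == "rotation")
    rotateImage(arr, value, center = config@fixation, fill = config@fillValue)
  else
    zoomImage(arr, value, center = config@fixation, fill = config@fillValue)
  lpT <- toLogPolar(transformed, config)
  lpO <- toLogPolar(arr, config)

  C <- dim(lpO)[1]
  keep <- seq_len(config@nRho) > excludeRings &
    seq_len(config@nRho) <= config@nRho - excludeOuter
  a <- c(); b <- c()
  for (ch in seq_len(C)) {
    m <- lpO@.Data[ch, , ]
    sh <- if (kind == "rotation")
      .shiftMatrix(m, shift[2], axis = "col", circular = TRUE)
    else
      .shiftMatrix(m, shift[1], axis = "row", circular = FALSE)
    ok <- sh$valid & keep
    a <- c(a, lpT@.Data[ch, , ][ok])
    b <- c(b, sh$values[ok])
  }
  if (length(a) < 3) stop("no jointly valid region to compare")
  # interpolation of a constant leaves ~1e-17 rounding residue, so compare
  # the spread against a tolerance rather than exact zero
  if (sd(a) < 1e-12 || sd(b) < 1e-12)
    stop("correlation undefined for constant images")
  cor(a, b)
}
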