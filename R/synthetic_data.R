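## Deterministic synthetic-scene generator and fixture benchmark.
##
## Scenes contain a single bright object of a small closed class set (disk,
## square, cross, ring) rendered analytically (signed-distance functions with
## a one-pixel soft edge) on a band-limited noise background, with exact
## axis-aligned bounding boxes and landmark keypoints. The generator stands in
## for photographic benchmarks: objects have a canonical ("upright")
## orientation with a small jitter, a controlled position and scale, and the
## background is never flat so correlation-based equivariance measures are
## well conditioned.

.sceneClasses <- c("disk", "square", "cross", "ring")

## signed distance of points (in object frame, already rotated/centered) to
## each shape of half-size s; cross bar half-width is 0.3 * s, ring inner
## radius 0.55 * s.
.shapeSdf <- function(shape, px, py, s) {
  switch(shape,
    disk = sqrt(px^2 + py^2) - s,
    ring = {
      r <- sqrt(px^2 + py^2)
      pmax(r - s, 0.55 * s - r)
    },
    square = pmax(abs(px), abs(py)) - s,
    cross = {
      w <- 0.3 * s
      b1 <- pmax(abs(px) - s, abs(py) - w)
      b2 <- pmax(abs(px) - w, abs(py) - s)
      pmin(b1, b2)
    },
    stop("unknown shape: ", shape))
}

## analytic half-extents (x, y) of the shape rotated by phi
.shapeExtent <- function(shape, s, phi) {
  ca <- abs(cos(phi)); sa <- abs(sin(phi))
  switch(shape,
    disk = c(s, s),
    ring = c(s, s),
    square = c(s * (ca + sa), s * (ca + sa)),
    cross = {
      w <- 0.3 * s
      c(max(s * ca + w * sa, w * ca + s * sa),
        max(s * sa + w * ca, w * sa + s * ca))
    })
}

## landmark keypoints in object frame (center + extremal points)
.shapeKeypoints <- function(shape, s) {
  switch(shape,
    disk = rbind(c(0, 0), c(s, 0), c(-s, 0), c(0, s), c(0, -s)),
    ring = rbind(c(0, 0), c(s, 0), c(-s, 0), c(0, s), c(0, -s)),
    square = rbind(c(0, 0), c(s, s), c(s, -s), c(-s, s), c(-s, -s)),
    cross = rbind(c(0, 0), c(s, 0), c(-s, 0), c(0, s), c(0, -s)))
}

#' Band-limited noise texture
#'
#' Gaussian noise on a coarse 9 x 9 node grid, interpolated to the working
#' resolution with a normalized Gaussian kernel (bandwidth 0.6 of the node
#' spacing) and clamped to [0, 1]: smooth everywhere, never flat, and free
#' of energy near the pixel scale. Used as the scene background and as the
#' fixture of choice for equivariance measurements — correlations on it are
#' well conditioned because variance is spread over the whole frame, and
#' the smoothness keeps resampling error far below the signal.
#'
#' @param seed integer seed.
#' @param imageSize raster side in pixels.
#' @param contrast noise standard deviation.
#' @param bgMean mean level.
#' @return an [ImageRaster].
#' @export
generateTexture <- function(seed, imageSize = 64L, contrast = 0.1,
                            bgMean = 0.4) {
  N <- as.integer(imageSize)
  vals <- .withSeed(seed, matrix(rnorm(81, mean = bgMean, sd = contrast),
                                 9, 9))       # [node_y, node_x]
  nodes <- seq(-1, 1, length.out = 9)
  sig <- 0.6 * (nodes[2] - nodes[1])
  xy <- .gridXY(N, N)
  wx <- exp(-outer(xy$x, nodes, `-`)^2 / (2 * sig^2))
  wy <- exp(-outer(xy$y, nodes, `-`)^2 / (2 * sig^2))
  bg <- rowSums((wy %*% vals) * wx) / (rowSums(wy) * rowSums(wx))
  ImageRaster(matrix(pmin(pmax(bg, 0), 1), N, N))
}

#' Render one synthetic scene
#'
#' Deterministically renders a single labelled object on a band-limited noise
#' background and returns the image together with its exact annotations. The
#' background is Gaussian noise on a coarse grid, bilinearly upsampled to the
#' working resolution, so it is smooth but never constant. The object is
#' rendered from a signed-distance function with a one-pixel soft edge; the
#' bounding box is the analytic axis-aligned extent of the zero contour and
#' the keypoints are the object's defining landmarks (center plus extremal
#' points), all in normalized coordinates.
#'
#' @param class object class: `"disk"`, `"square"`, `"cross"` or `"ring"`.
#' @param position normalized object center `(x, y)`.
#' @param scale object half-size in normalized units (must leave the object
#'   smaller than the frame).
#' @param orientation rotation of the object in radians.
#' @param seed integer seed driving the background noise.
#' @param imageSize raster side in pixels.
#' @param contrast standard deviation of the background noise.
#' @param bgMean mean background level.
#' @param fgValue object intensity.
#' @return list with elements `image` ([ImageRaster]), `bbox` (xMin, yMin,
#'   xMax, yMax), `keypoints` (k x 2 matrix), `label` (class name), `center`,
#'   `scale`.
#' @examples
#' sc <- generateScene("disk", position = c(0.3, 0), scale = 0.2, seed = 7)
#' sc$bbox   # (0.1, -0.2, 0.5, 0.2)
#' @export
generateScene <- function(class, position = c(0, 0), scale = 0.2,
                          orientation = 0, seed = 1L, imageSize = 64L,
                          contrast = 0.1, bgMean = 0.4, fgValue = 0.95) {
  class <- match.arg(class, .sceneClasses)
  if (scale <= 0) stop("scale must be positive")
  ext <- .shapeExtent(class, scale, orientation)
  if (any(ext >= 1)) stop("object larger than the frame")
  N <- as.integer(imageSize)

  bg <- generateTexture(seed, imageSize = N, contrast = contrast,
                        bgMean = bgMean)@.Data[1, , ]

  pc <- .pixelCenters(N, N)
  xs <- matrix(pc$x, N, N, byrow = TRUE)
  ys <- matrix(pc$y, N, N)
  dx <- xs - position[1]; dy <- ys - position[2]
  ca <- cos(orientation); sa <- sin(orientation)
  px <- ca * dx + sa * dy          # rotate into the object frame
  py <- -sa * dx + ca * dy
  sdf <- .shapeSdf(class, px, py, scale)
  edge <- 2 / N                    # one-pixel transition band
  alpha <- pmin(pmax(0.5 - sdf / edge, 0), 1)
  img <- bg * (1 - alpha) + fgValue * alpha

  kp <- .shapeKeypoints(class, scale)
  R <- matrix(c(ca, sa, -sa, ca), 2, 2)   # object frame -> image frame
  kpImg <- sweep(kp %*% t(R), 2, position, `+`)
  bbox <- c(position[1] - ext[1], position[2] - ext[2],
            position[1] + ext[1], position[2] + ext[2])
  list(image = ImageRaster(img), bbox = bbox, keypoints = kpImg,
       label = class, center = position, scale = scale)
}

#' Crop the smallest object-centered square
#'
#' Extracts the smallest square containing a bounding box, centered on the
#' box center but clamped so the square stays inside the frame, and resizes
#' it to the requested resolution. This is the "focus" view of a scene: the
#' center of gaze is moved to the annotated object.
#'
#' @param image an `ImageRaster`, array, or matrix.
#' @param bbox normalized `(xMin, yMin, xMax, yMax)`.
#' @param resolution output side in pixels (defaults to the source height).
#' @return an [ImageRaster].
#' @export
focusCrop <- function(image, bbox, resolution = NULL) {
  arr <- .rasterArray(image)
  g <- .focusGeometry(bbox)
  N <- if (is.null(resolution)) dim(arr)[2] else as.integer(resolution)
  xy <- .gridXY(N, N)
  v <- .bilinearSample(arr, g$cx + xy$x * g$half, g$cy + xy$y * g$half)
  ImageRaster(array(v, c(dim(arr)[1], N, N)))
}

## square geometry of the focus crop: center (clamped into the frame) and
## half-side
.focusGeometry <- function(bbox) {
  if (length(bbox) != 4 || any(!is.finite(bbox)) ||
      bbox[1] >= bbox[3] || bbox[2] >= bbox[4])
    stop("degenerate bounding box")
  half <- max(bbox[3] - bbox[1], bbox[4] - bbox[2]) / 2
  half <- min(half, 1)
  cx <- min(max((bbox[1] + bbox[3]) / 2, -1 + half), 1 - half)
  cy <- min(max((bbox[2] + bbox[4]) / 2, -1 + half), 1 - half)
  list(cx = cx, cy = cy, half = half)
}

#' Generate a paired fixture benchmark (regular and focus variants)
#'
#' Draws `n` balanced scenes with uniformly distributed positions and scales
#' and a small orientation jitter about the canonical upright pose (the
#' orientation regularity of curated photographs is what makes rotation a
#' meaningful out-of-distribution perturbation). The `focus` variant recrops
#' every scene to the smallest square containing its bounding box, recentring
#' the object, with all annotations mapped into crop coordinates.
#'
#' @param n number of scenes (>= 1).
#' @param seed integer seed; the same seed reproduces the datasets exactly.
#' @param classes number of object classes (2 to 4).
#' @param imageSize raster side in pixels.
#' @param scaleRange range of object half-sizes.
#' @param positionRange positions are uniform on `[-positionRange,
#'   positionRange]` per axis (with `centerBias` they are drawn from a
#'   triangular distribution peaked at the center instead).
#' @param orientationJitter half-width of the uniform orientation jitter in
#'   radians.
#' @param contrast background noise standard deviation.
#' @param centerBias emulate a photographer's bias toward centered objects.
#' @return list with elements `regular` and `focus`, both
#'   [FixtureDataset-class] objects.
#' @export
makeFixtureBenchmark <- function(n, seed = 1L, classes = 4L, imageSize = 64L,
                                 scaleRange = c(0.25, 0.45),
                                 positionRange = 0.35,
                                 orientationJitter = pi / 12,
                                 contrast = 0.1, centerBias = FALSE) {
  if (n < 1) stop("n must be >= 1")
  classes <- as.integer(classes)
  if (classes < 2L || classes > 4L) stop("classes must be between 2 and 4")
  classNames <- .sceneClasses[seq_len(classes)]
  labels <- rep(seq_len(classes), length.out = n)

  pars <- .withSeed(seed, {
    pos <- matrix(runif(2 * n, -positionRange, positionRange), n, 2)
    if (centerBias)
      pos <- (pos + matrix(runif(2 * n, -positionRange, positionRange),
                           n, 2)) / 2
    list(pos = pos,
         scl = runif(n, scaleRange[1], scaleRange[2]),
         ori = runif(n, -orientationJitter, orientationJitter),
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })

  images <- vector("list", n); focImages <- vector("list", n)
  bboxes <- matrix(0, n, 4); focBboxes <- matrix(0, n, 4)
  kps <- vector("list", n); focKps <- vector("list", n)
  centers <- matrix(0, n, 2); focCenters <- matrix(0, n, 2)
  scales <- numeric(n); focScales <- numeric(n)
  for (i in seq_len(n)) {
    sc <- generateScene(classNames[labels[i]], position = pars$pos[i, ],
                        scale = pars$scl[i], orientation = pars$ori[i],
                        seed = pars$seeds[i], imageSize = imageSize,
                        contrast = contrast)
    images[[i]] <- sc$image
    bboxes[i, ] <- sc$bbox
    kps[[i]] <- sc$keypoints
    centers[i, ] <- sc$center
    scales[i] <- sc$scale

    g <- .focusGeometry(sc$bbox)
    focImages[[i]] <- focusCrop(sc$image, sc$bbox, resolution = imageSize)
    shift <- c(g$cx, g$cy)
    focBboxes[i, ] <- c((sc$bbox[1:2] - shift) / g$half,
                        (sc$bbox[3:4] - shift) / g$half)
    focKps[[i]] <- sweep(sc$keypoints, 2, shift) / g$half
    focCenters[i, ] <- (sc$center - shift) / g$half
    focScales[i] <- sc$scale / g$half
  }
  mk <- function(imgs, bb, kk, cc, ss, variant)
    new("FixtureDataset", images = imgs, labels = as.integer(labels),
        classNames = classNames, bboxes = bb, keypoints = kk, centers = cc,
        scales = ss, variant = variant)
  list(regular = mk(images, bboxes, kps, centers, scales, "regular"),
       focus = mk(focImages, focBboxes, focKps, focCenters, focScales,
                  "focus"))
}

#' Subset a fixture dataset
#'
#' @param x a [FixtureDataset-class].
#' @param i integer or logical index of scenes to keep.
#' @param j,drop,... ignored.
#' @return a [FixtureDataset-class].
#' @export
setMethod("[", "FixtureDataset", function(x, i, j, ..., drop = FALSE) {
  new("FixtureDataset", images = x@images[i], labels = x@labels[i],
      classNames = x@classNames, bboxes = x@bboxes[i, , drop = FALSE],
      keypoints = x@keypoints[i], centers = x@centers[i, , drop = FALSE],
      scales = x@scales[i], variant = x@variant)
})
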