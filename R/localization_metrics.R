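## Ground-truth construction on the fixation grid and the localization
## scores used to judge likelihood maps: pointing game (peak inside the
## mask), in/out mean activation and their ratio, and IoU curves over a
## threshold sweep.

#' Rasterize a bounding box onto the fixation grid
#'
#' A grid cell counts as inside the box when its fixation coordinate falls
#' inside the box, boundary inclusive (`method = "center"`). The
#' `"coverage"` variant instead requires at least half of the cell's
#' catchment area (the Voronoi region of the fixation, clipped to the frame)
#' to overlap the box. If no cell qualifies — a box smaller than a cell —
#' the cell nearest the box center is marked, so the mask is never empty.
#'
#' @param bbox normalized `(xMin, yMin, xMax, yMax)`, non-degenerate.
#' @param G fixation grid side.
#' @param method cell membership rule.
#' @return a [GroundTruth-class] with source `"box"`.
#' @export
boxToMask <- function(bbox, G = 11L, method = c("center", "coverage")) {
  method <- match.arg(method)
  if (length(bbox) != 4 || any(!is.finite(bbox)) ||
      bbox[1] >= bbox[3] || bbox[2] >= bbox[4])
    stop("degenerate bounding box")
  fg <- fixationGrid(G)
  xs <- fg[1, , 1]; ys <- fg[, 1, 2]
  if (method == "center") {
    inx <- xs >= bbox[1] & xs <= bbox[3]
    iny <- ys >= bbox[2] & ys <= bbox[4]
    mask <- outer(iny, inx, `&`)
  } else {
    # cell catchment: half-spacing around each fixation, clipped to [-1, 1]
    h <- if (G == 1L) 1 else 1 / (G - 1)
    lo <- function(u) pmax(u - h, -1); hi <- function(u) pmin(u + h, 1)
    ovx <- pmax(0, pmin(hi(xs), bbox[3]) - pmax(lo(xs), bbox[1])) /
      (hi(xs) - lo(xs))
    ovy <- pmax(0, pmin(hi(ys), bbox[4]) - pmax(lo(ys), bbox[2])) /
      (hi(ys) - lo(ys))
    mask <- outer(ovy, ovx) >= 0.5
  }
  if (!any(mask)) {
    cx <- (bbox[1] + bbox[3]) / 2; cy <- (bbox[2] + bbox[4]) / 2
    mask[which.min(abs(ys - cy)), which.min(abs(xs - cx))] <- TRUE
  }
  new("GroundTruth", bbox = as.numeric(bbox),
      heatmap = mask * 1, mask = mask, source = "box")
}

#' Gaussian heat values at arbitrary points
#'
#' The maximum over per-keypoint isotropic Gaussians, each with peak 1 at
#' its keypoint and standard deviation `sigma`. The 0.2-level contour of a
#' lone keypoint is the circle of radius `sigma * sqrt(2 * log(5))`.
#'
#' @param x,y coordinates at which to evaluate.
#' @param keypoints k x 2 matrix of keypoint coordinates.
#' @param sigma Gaussian standard deviation (> 0).
#' @return numeric vector of heat values in (0, 1].
#' @export
gaussianHeatValues <- function(x, y, keypoints, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  keypoints <- rbind(keypoints)
  out <- rep(0, length(x))
  for (k in seq_len(nrow(keypoints))) {
    d2 <- (x - keypoints[k, 1])^2 + (y - keypoints[k, 2])^2
    out <- pmax(out, exp(-d2 / (2 * sigma^2)))
  }
  out
}

#' Keypoint-derived Gaussian heat-map ground truth
#'
#' Builds a fine heat map as the per-pixel maximum of isotropic Gaussians
#' centered on the keypoints (peak 1, standard deviation
#' `sigmaFactor * objectScale` — "proportional to object size"), downsamples
#' it to the G x G fixation grid by area averaging, renormalizes the peak to
#' 1, and thresholds at `threshold` (default 0.2) for the binary contour
#' mask.
#'
#' @param keypoints k x 2 matrix of normalized keypoints (at least one).
#' @param objectScale object size in normalized units (> 0).
#' @param G fixation grid side.
#' @param sigmaFactor proportionality constant for the Gaussian width.
#' @param threshold binary contour threshold.
#' @param oversample fine-raster cells per grid cell and axis.
#' @return a [GroundTruth-class] with source `"keypoints"`.
#' @export
keypointsToHeatmap <- function(keypoints, objectScale, G = 11L,
                               sigmaFactor = 0.25, threshold = 0.2,
                               oversample = 11L) {
  keypoints <- rbind(keypoints)
  if (nrow(keypoints) < 1) stop("at least one keypoint is required")
  if (objectScale <= 0) stop("objectScale must be positive")
  sigma <- sigmaFactor * objectScale
  R <- G * as.integer(oversample)
  xy <- .gridXY(R, R)
  fine <- matrix(gaussianHeatValues(xy$x, xy$y, keypoints, sigma), R, R)
  # area-average oversample x oversample blocks down to G x G
  blk <- as.integer(oversample)
  down <- matrix(0, G, G)
  for (i in seq_len(G)) for (j in seq_len(G))
    down[i, j] <- mean(fine[((i - 1) * blk + 1):(i * blk),
                            ((j - 1) * blk + 1):(j * blk)])
  down <- down / max(down)
  new("GroundTruth", bbox = rep(NA_real_, 4), heatmap = down,
      mask = down >= threshold, source = "keypoints")
}

#' Pointing game
#'
#' Success when the map's peak cell (row-major tie-breaking) falls inside
#' the ground-truth mask. Invariant to any strictly monotone rescaling of
#' the map.
#'
#' @param map a [LikelihoodMap-class] or plain matrix.
#' @param gt a [GroundTruth-class] of the same grid size.
#' @return logical.
#' @export
pointingGame <- function(map, gt) {
  m <- if (is(map, "LikelihoodMap")) map@values else map
  if (!identical(dim(m), dim(gt@mask))) stop("map and mask shapes differ")
  pk <- .peakCell(m)
  gt@mask[pk[1], pk[2]]
}

#' Energy-based pointing score
#'
#' The fraction of the map's total mass falling inside the mask — a softer
#' companion to the peak-based [pointingGame()].
#'
#' @inheritParams pointingGame
#' @return numeric in [0, 1].
#' @export
energyPointingScore <- function(map, gt) {
  m <- if (is(map, "LikelihoodMap")) map@values else map
  if (!identical(dim(m), dim(gt@mask))) stop("map and mask shapes differ")
  tot <- sum(m)
  if (tot == 0) return(0)
  sum(m[gt@mask]) / tot
}

#' Mean activation inside/outside the mask
#'
#' Arithmetic means of the map over mask-inside and mask-outside cells and
#' their ratio; a high ratio means the map concentrates likelihood on the
#' object. The ratio is `NA` (flagged undefined) when the mask covers the
#' whole grid or the outside mean is zero.
#'
#' @inheritParams pointingGame
#' @return list with `meanIn`, `meanOut`, `ratio`.
#' @export
inOutStats <- function(map, gt) {
  m <- if (is(map, "LikelihoodMap")) map@values else map
  if (!identical(dim(m), dim(gt@mask))) stop("map and mask shapes differ")
  inside <- gt@mask
  meanIn <- mean(m[inside])
  if (all(inside)) return(list(meanIn = meanIn, meanOut = NA_real_,
                               ratio = NA_real_))
  meanOut <- mean(m[!inside])
  list(meanIn = meanIn, meanOut = meanOut,
       ratio = if (meanOut > 0) meanIn / meanOut else NA_real_)
}

#' IoU curve over a threshold sweep
#'
#' Binarizes the map at each threshold (`map >= t`) and computes the
#' intersection-over-union with the ground-truth mask; an empty union gives
#' IoU 0. The peak IoU and the first threshold attaining it are reported.
#'
#' @inheritParams pointingGame
#' @param thresholds thresholds in [0, 1] (default 101 uniform steps).
#' @return list with `thresholds`, `iou`, `peakIoU`, `peakThreshold`.
#' @export
iouCurve <- function(map, gt, thresholds = seq(0, 1, length.out = 101)) {
  m <- if (is(map, "LikelihoodMap")) map@values else map
  if (!identical(dim(m), dim(gt@mask))) stop("map and mask shapes differ")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  iou <- vapply(thresholds, function(t) {
    bin <- m >= t
    u <- sum(bin | gt@mask)
    if (u == 0) 0 else sum(bin & gt@mask) / u
  }, numeric(1))
  k <- which.max(iou)
  list(thresholds = thresholds, iou = iou,
       peakIoU = iou[k], peakThreshold = thresholds[k])
}

#' Aggregate localization report over a dataset
#'
#' Combines the per-image localization scores: pointing rate, energy
#' pointing score, in/out statistics (both the ratio of dataset means and
#' the mean of per-image ratios), and the mean IoU curve with its peak.
#' When a classifier and the source images are supplied, central-fixation
#' accuracy, saccade accuracy and their difference are reported as well.
#'
#' @param maps list of [LikelihoodMap-class].
#' @param gts list of [GroundTruth-class], aligned with `maps`.
#' @param clf optional classifier for the accuracy block.
#' @param images,labels optional source images and true labels, aligned
#'   with `maps` (required with `clf`).
#' @param thresholds IoU threshold grid.
#' @return list of aggregate scores.
#' @export
datasetReport <- function(maps, gts, clf = NULL, images = NULL,
                          labels = NULL,
                          thresholds = seq(0, 1, length.out = 101)) {
  n <- length(maps)
  if (n == 0 || length(gts) != n) stop("maps and gts must align")
  pointing <- vapply(seq_len(n), function(i)
    pointingGame(maps[[i]], gts[[i]]), logical(1))
  energy <- vapply(seq_len(n), function(i)
    energyPointingScore(maps[[i]], gts[[i]]), numeric(1))
  stats <- lapply(seq_len(n), function(i) inOutStats(maps[[i]], gts[[i]]))
  meanIn <- mean(vapply(stats, `[[`, numeric(1), "meanIn"))
  meanOut <- mean(vapply(stats, `[[`, numeric(1), "meanOut"))
  ratios <- vapply(stats, `[[`, numeric(1), "ratio")
  curves <- vapply(seq_len(n), function(i)
    iouCurve(maps[[i]], gts[[i]], thresholds)$iou, numeric(length(thresholds)))
  meanCurve <- rowMeans(curves)
  k <- which.max(meanCurve)
  rep <- list(pointingRate = mean(pointing),
              energyPointing = mean(energy),
              meanIn = meanIn, meanOut = meanOut,
              ratioOfMeans = meanIn / meanOut,
              meanOfRatios = mean(ratios, na.rm = TRUE),
              iouThresholds = thresholds, iouCurve = meanCurve,
              peakIoU = meanCurve[k], peakThreshold = thresholds[k])
  if (!is.null(clf)) {
    if (is.null(images) || is.null(labels) || length(images) != n ||
        length(labels) != n)
      stop("images and labels must align with maps when clf is given")
    p <- predictProbs(clf, images)
    rep$centralAccuracy <- mean(max.col(p, ties.method = "first") == labels)
    sacc <- vapply(seq_len(n), function(i) {
      pk <- .peakCell(maps[[i]]@values)
      fix <- maps[[i]]@fixations[pk[1], pk[2], ]
      cr <- cropAtFixation(images[[i]], fix,
                           resolution = inputResolution(clf)[1])
      which.max(predictProbs(clf, list(cr$image))[1, ]) == labels[i]
    }, logical(1))
    rep$saccadeAccuracy <- mean(sacc)
    rep$accuracyImprovement <- rep$saccadeAccuracy - rep$centralAccuracy
  }
  rep
}
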