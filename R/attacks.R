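## Worst-case geometric attack protocol and accuracy sweeps.
##
## An attack evaluates the classifier at every value of a parameter grid
## (rotation angles, zoom factors, or roll-to-fixation placements), picks the
## parameter maximizing the per-image cross-entropy loss, and reports the
## label predicted at that worst parameter. Perturbations are applied in
## image space; a retinotopic classifier foveates internally afterwards
## (perturb -> foveate -> classify). Ties break to the first maximizer in
## grid order, so results are deterministic.

#' Cross-entropy loss of a probability vector
#'
#' `-log(p[label])`, with probabilities floored at 1e-12 so confidently wrong
#' classifiers produce finite losses.
#'
#' @param probs probability vector (or one row of a [predictProbs()] matrix).
#' @param label 1-based true label.
#' @return non-negative loss.
#' @examples
#' crossEntropyLoss(rep(1 / 1000, 1000), 17)   # log(1000)
#' @export
crossEntropyLoss <- function(probs, label) {
  probs <- as.numeric(probs)
  if (length(label) != 1 || is.na(label) || label < 1 || label > length(probs))
    stop("label out of range")
  -log(max(probs[label], 1e-12))
}

## shared attack engine: images[[i]] corresponds to grid row i
.attackEngine <- function(clf, images, label, kind, grid, params) {
  p <- predictProbs(clf, images)
  if (label < 1 || label > ncol(p)) stop("label out of range")
  losses <- -log(pmax(p[, label], 1e-12))
  wi <- which.max(losses)                  # first maximizer in grid order
  pred <- which.max(p[wi, ])
  new("AttackResult", kind = kind, worstParam = params[[wi]],
      worstLoss = losses[wi], losses = losses, grid = grid,
      predictedLabel = as.integer(pred), trueLabel = as.integer(label),
      correct = pred == label)
}

#' Worst-case rotation attack
#'
#' Rotates the image about the frame center by every angle of the grid,
#' classifies all rotations, and keeps the angle that maximizes the
#' cross-entropy loss; the reported prediction is the arg-max label at that
#' worst angle. The default grid spans -180 to +180 degrees in 15-degree
#' steps.
#'
#' @param clf a classifier satisfying the [predictProbs()] contract.
#' @param image an `ImageRaster`, array, or matrix.
#' @param label 1-based true label.
#' @param angles rotation angles in degrees (non-empty).
#' @return an [AttackResult-class].
#' @export
rotationAttack <- function(clf, image, label,
                           angles = seq(-180, 180, by = 15)) {
  if (length(angles) == 0) stop("angles must be non-empty")
  arr <- .rasterArray(image)
  imgs <- lapply(angles, function(a) rotateImage(arr, a * pi / 180))
  .attackEngine(clf, imgs, label, "rotation", matrix(angles, ncol = 1),
                as.list(angles))
}

#' Worst-case zoom attack
#'
#' As [rotationAttack()], with zoom factor as the attacked parameter. The
#' default grid covers the zoom-out range only, 11 geometric steps from x1
#' down to x0.1 (zoom-in attacks degenerate: maximal magnification always
#' wins).
#'
#' @inheritParams rotationAttack
#' @param factors positive zoom factors.
#' @return an [AttackResult-class].
#' @export
zoomAttack <- function(clf, image, label,
                       factors = 10^seq(0, -1, length.out = 11)) {
  if (length(factors) == 0 || any(factors <= 0))
    stop("factors must be positive")
  arr <- .rasterArray(image)
  imgs <- lapply(factors, function(f) zoomImage(arr, f))
  .attackEngine(clf, imgs, label, "zoom", matrix(factors, ncol = 1),
                as.list(factors))
}

#' Worst-case translation (fixation) attack
#'
#' Places each point of a linear G x G fixation grid at the frame center by
#' circularly rolling the image, classifies every placement, and keeps the
#' placement maximizing the loss. `worstParam` is the attacked fixation point
#' in normalized coordinates; ties break row-major.
#'
#' @inheritParams rotationAttack
#' @param gridSize side of the fixation grid (>= 1; 11 gives the standard
#'   121 placements).
#' @return an [AttackResult-class].
#' @export
translationAttack <- function(clf, image, label, gridSize = 11L) {
  if (gridSize < 1) stop("gridSize must be >= 1")
  arr <- .rasterArray(image)
  fg <- fixationGrid(gridSize)
  pts <- cbind(as.vector(t(fg[, , 1])), as.vector(t(fg[, , 2])))  # row-major
  imgs <- lapply(seq_len(nrow(pts)), function(i)
    translateRoll(arr, c(-pts[i, 1] / 2, -pts[i, 2] / 2)))
  .attackEngine(clf, imgs, label, "translation", pts,
                lapply(seq_len(nrow(pts)), function(i) pts[i, ]))
}

## apply one transform of a sweep to an image
.sweepTransform <- function(kind, arr, value) {
  switch(kind,
    rotation = rotateImage(arr, value * pi / 180),
    zoom = zoomImage(arr, value),
    stop("sweep kind must be 'rotation' or 'zoom'"))
}

#' Accuracy sweep over a transform grid
#'
#' Mean top-1 accuracy of a classifier on a fixture dataset at each value of
#' a rotation-angle (degrees) or zoom-factor grid. The grid is sorted
#' ascending; each grid value is evaluated over the whole dataset.
#'
#' @param clf a classifier satisfying the [predictProbs()] contract.
#' @param data a [FixtureDataset-class] (non-empty).
#' @param kind `"rotation"` or `"zoom"`.
#' @param grid parameter values (angles in degrees, or zoom factors).
#' @return a [SweepCurve-class].
#' @export
sweepAccuracy <- function(clf, data, kind = c("rotation", "zoom"),
                          grid = NULL) {
  kind <- match.arg(kind)
  if (length(data) == 0) stop("dataset is empty")
  if (is.null(grid))
    grid <- if (kind == "rotation") seq(-180, 180, by = 15)
            else 10^seq(-1, 1, length.out = 21)
  grid <- sort(unique(grid))
  acc <- vapply(grid, function(v) {
    imgs <- lapply(data@images, function(im)
      .sweepTransform(kind, .rasterArray(im), v))
    p <- predictProbs(clf, imgs)
    mean(max.col(p, ties.method = "first") == data@labels)
  }, numeric(1))
  new("SweepCurve", kind = kind, grid = as.numeric(grid), accuracy = acc)
}

#' Dataset accuracy under a worst-case attack
#'
#' Runs the chosen attack on every scene of a fixture dataset and returns the
#' fraction of scenes still classified correctly at their individually worst
#' parameter, together with the per-scene results.
#'
#' @inheritParams sweepAccuracy
#' @param kind `"rotation"`, `"zoom"` or `"translation"`.
#' @param ... passed to the attack function (`angles`, `factors`,
#'   `gridSize`).
#' @return list with `accuracy` and the per-image `results`.
#' @export
attackAccuracy <- function(clf, data,
                           kind = c("rotation", "zoom", "translation"),
                           ...) {
  kind <- match.arg(kind)
  if (length(data) == 0) stop("dataset is empty")
  fn <- switch(kind, rotation = rotationAttack, zoom = zoomAttack,
               translation = translationAttack)
  results <- lapply(seq_len(length(data)), function(i)
    fn(clf, data@images[[i]], data@labels[i], ...))
  list(accuracy = mean(vapply(results, function(r) r@correct, logical(1))),
       results = results)
}

#' Per-fixation accuracy map under rolled placements
#'
#' The translation-attack companion view: mean dataset accuracy when each
#' fixation-grid point is rolled to the frame center, reported per grid
#' position rather than per-image worst case.
#'
#' @inheritParams sweepAccuracy
#' @param gridSize side of the fixation grid.
#' @return gridSize x gridSize accuracy matrix (rows = y, columns = x).
#' @export
translationAccuracyMap <- function(clf, data, gridSize = 11L) {
  if (length(data) == 0) stop("dataset is empty")
  fg <- fixationGrid(gridSize)
  acc <- matrix(0, gridSize, gridSize)
  for (i in seq_len(gridSize)) for (j in seq_len(gridSize)) {
    imgs <- lapply(data@images, function(im)
      translateRoll(.rasterArray(im),
                    c(-fg[i, j, 1] / 2, -fg[i, j, 2] / 2)))
    p <- predictProbs(clf, imgs)
    acc[i, j] <- mean(max.col(p, ties.method = "first") == data@labels)
  }
  acc
}
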