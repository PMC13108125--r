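## The visual-search protocol: sweep a grid of fixation points over an
## image, crop the largest possible view at each fixation, classify every
## view in one batch, and read off the likelihood the classifier assigns to
## a cued label. The resulting G x G map is a saliency surface: its peak is
## the best place to "look" for the label, and a saccade to that peak
## usually classifies better than the central fixation.

#' Linear fixation grid
#'
#' G x G fixation points spanning the normalized frame [-1, 1]^2 inclusive
#' of the borders; `G = 1` gives the single central fixation. For the
#' standard `G = 11`, the center cell (row 6, column 6; coordinate (5, 5)
#' 0-based) sits exactly at the image center.
#'
#' @param G grid side (>= 1).
#' @return G x G x 2 array; `[i, j, ]` is the (x, y) fixation of row i
#'   (y, downward) and column j (x, rightward).
#' @export
fixationGrid <- function(G) {
  G <- as.integer(G)
  if (is.na(G) || G < 1L) stop("G must be >= 1")
  u <- if (G == 1L) 0 else seq(-1, 1, length.out = G)
  fg <- array(0, c(G, G, 2L))
  fg[, , 1] <- matrix(u, G, G, byrow = TRUE)
  fg[, , 2] <- matrix(u, G, G)
  fg
}

#' Crop the largest sample at a fixation point
#'
#' The crop radius is the distance from the fixation point to the nearest
#' image border, floored at `minRatio` (so a border fixation still yields a
#' 1:10-scale sample and the central fixation yields the whole image). The
#' square of that half-side, centered on the fixation, is resampled
#' bilinearly to the requested resolution. Near the borders the floored
#' radius can reach outside the frame; those samples are filled with
#' `fill`.
#'
#' @param image an `ImageRaster`, array, or matrix.
#' @param fixation normalized fixation `(x, y)` in [-1, 1]^2.
#' @param minRatio minimum crop radius as a fraction of the half-frame
#'   (default 0.1).
#' @param resolution output side in pixels (defaults to the source height).
#' @param fill fill value for out-of-frame samples.
#' @return list with `image` (the resampled crop, an [ImageRaster]) and
#'   `radius` (the normalized crop radius).
#' @export
cropAtFixation <- function(image, fixation, minRatio = 0.1,
                           resolution = NULL, fill = 0) {
  arr <- .rasterArray(image)
  N <- if (is.null(resolution)) dim(arr)[2] else as.integer(resolution)
  cr <- .cropArray(arr, fixation, minRatio, N, fill)
  list(image = ImageRaster(cr$arr), radius = cr$radius)
}

.cropArray <- function(arr, fixation, minRatio, N, fill = 0) {
  if (length(fixation) != 2 || any(!is.finite(fixation)) ||
      any(abs(fixation) > 1))
    stop("fixation must lie inside [-1, 1]^2")
  if (minRatio <= 0 || minRatio > 1) stop("minRatio must be in (0, 1]")
  radius <- max(min(1 - abs(fixation[1]), 1 - abs(fixation[2])), minRatio)
  xy <- .gridXY(N, N)
  v <- .bilinearSample(arr, fixation[1] + xy$x * radius,
                       fixation[2] + xy$y * radius, fill = fill)
  list(arr = array(v, c(dim(arr)[1], N, N)), radius = radius)
}

## classify all G^2 fixation crops in one batch; returns the full
## probability matrix plus crop metadata (shared by the map builders)
.fixationProbs <- function(clf, image, G, minRatio = 0.1) {
  arr <- .rasterArray(image)
  fg <- fixationGrid(G)
  res <- inputResolution(clf)[1]
  crops <- vector("list", G * G)
  radii <- matrix(0, G, G)
  k <- 0L
  for (i in seq_len(G)) for (j in seq_len(G)) {   # row-major
    k <- k + 1L
    cr <- .cropArray(arr, fg[i, j, ], minRatio, res)
    crops[[k]] <- cr$arr
    radii[i, j] <- cr$radius
  }
  list(p = predictProbs(clf, crops), fixations = fg, radii = radii)
}

#' Likelihood map of a label over a fixation grid
#'
#' For every fixation of a linear G x G grid, crops the largest sample
#' (see [cropAtFixation()]), lets the classifier process it (the classifier
#' applies its own circular mask or log-polar preprocessing), and records
#' the probability assigned to the cued label. All G^2 views are submitted
#' to the classifier as a single batch.
#'
#' @param clf a classifier satisfying the [predictProbs()] contract.
#' @param image an `ImageRaster`, array, or matrix.
#' @param label 1-based cued label.
#' @param G fixation grid side (default 11).
#' @param minRatio minimum crop ratio (default 0.1).
#' @return a [LikelihoodMap-class].
#' @export
likelihoodMap <- function(clf, image, label, G = 11L, minRatio = 0.1) {
  fp <- .fixationProbs(clf, image, G, minRatio)
  if (label < 1 || label > ncol(fp$p)) stop("label out of range")
  vals <- matrix(fp$p[, label], G, G, byrow = TRUE)   # row-major fill
  new("LikelihoodMap", values = vals, fixations = fp$fixations,
      cropRadii = fp$radii, label = as.integer(label),
      mode = inputMode(clf))
}

#' Likelihood maps for several labels from one fixation sweep
#'
#' Runs the fixation sweep once, retains the full probability vectors, and
#' slices one map per requested label — the per-cell maps therefore sum to
#' one over all K labels.
#'
#' @inheritParams likelihoodMap
#' @param labels distinct 1-based labels.
#' @return list of [LikelihoodMap-class], one per label.
#' @export
multiLabelMaps <- function(clf, image, labels, G = 11L, minRatio = 0.1) {
  labels <- as.integer(labels)
  if (anyDuplicated(labels)) stop("labels must be distinct")
  fp <- .fixationProbs(clf, image, G, minRatio)
  if (any(labels < 1 | labels > ncol(fp$p))) stop("label out of range")
  lapply(labels, function(l)
    new("LikelihoodMap", values = matrix(fp$p[, l], G, G, byrow = TRUE),
        fixations = fp$fixations, cropRadii = fp$radii,
        label = l, mode = inputMode(clf)))
}

## row-major first maximizer of a matrix; returns c(row, col)
.peakCell <- function(m) {
  k <- which.max(as.vector(t(m)))        # row-major scan
  G <- ncol(m)
  c((k - 1L) %/% G + 1L, (k - 1L) %% G + 1L)
}

#' Saccade to the maximum-likelihood fixation and re-classify
#'
#' Computes the likelihood map for the cued label, moves the "eye" to the
#' arg-max fixation (row-major tie-breaking), re-runs the classifier on the
#' crop at that fixation, and reports top-1 correctness. With `G = 1` this
#' reduces to central-fixation classification.
#'
#' @inheritParams likelihoodMap
#' @return list with `fixation` (normalized coordinates), `probs` (the
#'   probability vector at the saccade target), `correct`, and `map` (the
#'   [LikelihoodMap-class] used for the choice).
#' @export
saccadeAndClassify <- function(clf, image, label, G = 11L, minRatio = 0.1) {
  map <- likelihoodMap(clf, image, label, G, minRatio)
  pk <- .peakCell(map@values)
  fix <- map@fixations[pk[1], pk[2], ]
  cr <- cropAtFixation(image, fix, minRatio = minRatio,
                       resolution = inputResolution(clf)[1])
  p <- predictProbs(clf, list(cr$image))[1, ]
  list(fixation = fix, probs = p,
       correct = which.max(p) == label, map = map)
}

#' Recenter likelihood maps on their peaks and aggregate
#'
#' Shifts every map so its peak cell lands at the center of a
#' (2G-1) x (2G-1) canvas, then averages cellwise over the maps that cover
#' each canvas cell. Cells never covered stay undefined — they are excluded
#' from the mean rather than treated as zero. The central cell is therefore
#' the mean of the per-map maxima, and the aggregate profile shows how
#' likelihood falls off with distance from the most salient fixation.
#'
#' @param maps non-empty list of [LikelihoodMap-class] objects sharing G.
#' @return an [AggregateMaps-class].
#' @export
recenterAndAggregate <- function(maps) {
  if (length(maps) == 0) stop("empty list of maps")
  G <- nrow(maps[[1]]@values)
  if (any(vapply(maps, function(m) nrow(m@values), integer(1)) != G))
    stop("all maps must share the same grid size")
  side <- 2L * G - 1L
  sums <- matrix(0, side, side)
  counts <- matrix(0L, side, side)
  for (m in maps) {
    pk <- .peakCell(m@values)
    rows <- seq_len(G) - pk[1] + G       # peak row -> canvas center G
    cols <- seq_len(G) - pk[2] + G
    sums[rows, cols] <- sums[rows, cols] + m@values
    counts[rows, cols] <- counts[rows, cols] + 1L
  }
  vals <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  new("AggregateMaps", values = vals, counts = counts)
}

#' Difference and log-odds-ratio maps between two aggregates
#'
#' Cellwise comparison of two recentered aggregates (e.g. two classifiers on
#' the same scenes): the plain difference `a - b` and the log-odds ratio
#' `logit(a) - logit(b)` with probabilities clamped to `[eps, 1 - eps]`.
#' Cells undefined in either operand are undefined in both outputs.
#'
#' @param a,b [AggregateMaps-class] objects on the same canvas.
#' @param eps clamping epsilon for the logit (default 1e-6).
#' @return list with matrices `difference` and `logOdds`.
#' @export
mapAlgebra <- function(a, b, eps = 1e-6) {
  if (!identical(dim(a@values), dim(b@values)))
    stop("canvas shapes differ")
  lo <- function(p) {
    p <- pmin(pmax(p, eps), 1 - eps)
    log(p / (1 - p))
  }
  list(difference = a@values - b@values,
       logOdds = lo(a@values) - lo(b@values))
}
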