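test_that("box rasterization follows fixation-in-box membership", {
  full <- boxToMask(c(-1, -1, 1, 1), G = 11)
  expect_equal(sum(full@mask), 121)
  # the central cell's own neighbourhood marks exactly cell (6, 6)
  ctr <- boxToMask(c(-1 / 11, -1 / 11, 1 / 11, 1 / 11), G = 11)
  expect_equal(which(ctr@mask), 6 + (6 - 1) * 11)
  # left half-plane x <= 0 includes the boundary column: 6 of 11 columns
  half <- boxToMask(c(-1, -1, 0, 1), G = 11)
  expect_equal(sum(half@mask), 6 * 11)
  # enumeration oracle on arbitrary boxes
  set.seed(8)
  fg <- fixationGrid(11)
  for (k in 1:5) {
    b <- sort(runif(2, -1, 1)); b2 <- sort(runif(2, -1, 1))
    bbox <- c(b[1], b2[1], b[2], b2[2])
    if (bbox[1] == bbox[3] || bbox[2] == bbox[4]) next
    got <- boxToMask(bbox, G = 11)@mask
    for (i in 1:11) for (j in 1:11) {
      p <- fg[i, j, ]
      inside <- p[1] >= bbox[1] && p[1] <= bbox[3] &&
                p[2] >= bbox[2] && p[2] <= bbox[4]
      if (any(got) && sum(got) > 1)
        expect_identical(got[i, j], inside)
    }
  }
  expect_error(boxToMask(c(0.5, 0, 0.2, 1)), "degenerate")
  # a sub-cell box still marks its nearest cell
  tiny <- boxToMask(c(0.31, 0.31, 0.33, 0.33), G = 11)
  expect_equal(sum(tiny@mask), 1)
})

test_that("the fractional-coverage membership variant behaves sensibly", {
  # a full-frame box includes every cell under either rule
  expect_equal(sum(boxToMask(c(-1, -1, 1, 1), 11, "coverage")@mask), 121)
  # boxes aligned with cell boundaries agree with the center rule
  expect_identical(boxToMask(c(-1, -1, 0, 1), 11, "coverage")@mask,
                   boxToMask(c(-1, -1, 0, 1), 11, "center")@mask)
  # a thin column-wide box captures exactly one column when it covers at
  # least half of that column's catchment
  thin <- boxToMask(c(0.15, -1, 0.25, 1), 11, "coverage")
  expect_equal(sum(thin@mask), 11)
  expect_true(all(which(thin@mask, arr.ind = TRUE)[, 2] == 7))
})

test_that("Gaussian heat maps obey their closed forms", {
  kp <- matrix(c(0, 0), 1, 2)
  sigma <- 0.2
  expect_equal(gaussianHeatValues(0, 0, kp, sigma), 1)
  expect_equal(gaussianHeatValues(sigma, 0, kp, sigma), exp(-1 / 2))
  # 0.2-contour radius: exp(-r^2 / (2 sigma^2)) = 0.2
  r02 <- sigma * sqrt(2 * log(5))
  expect_equal(gaussianHeatValues(r02, 0, kp, sigma), 0.2)
  expect_equal(r02 / sigma, 1.794, tolerance = 1e-3)
  # multi-keypoint combination by maximum keeps the peak at 1
  kp2 <- rbind(c(-0.3, 0), c(0.3, 0))
  expect_equal(max(gaussianHeatValues(c(-0.3, 0.3), c(0, 0), kp2, sigma)), 1)
  expect_error(gaussianHeatValues(0, 0, kp, -1), "sigma")
})

test_that("keypoint ground truth downsamples with peak renormalized to 1", {
  gt <- keypointsToHeatmap(matrix(c(0, 0), 1, 2), objectScale = 0.8, G = 11)
  expect_equal(max(gt@heatmap), 1)
  expect_true(gt@mask[6, 6])
  expect_identical(gt@source, "keypoints")
  expect_true(all(is.na(gt@bbox)))
  # mask equals thresholding the downsampled map at 0.2
  expect_identical(gt@mask, gt@heatmap >= 0.2)
  expect_error(keypointsToHeatmap(matrix(numeric(0), 0, 2), 0.5), "keypoint")
  expect_error(keypointsToHeatmap(matrix(0, 1, 2), 0), "objectScale")
})

test_that("pointing game follows the peak and the tie-break rule", {
  full <- boxToMask(c(-1, -1, 1, 1), G = 3)
  m <- matrix(0.2, 3, 3); m[2, 3] <- 0.9
  expect_true(pointingGame(m, full))
  # all-equal map peaks at cell (1, 1) under row-major tie-breaking
  mask <- matrix(TRUE, 3, 3); mask[1, 1] <- FALSE
  gt <- new("GroundTruth", bbox = c(-1, -1, 1, 1),
            heatmap = mask * 1, mask = mask, source = "box")
  expect_false(pointingGame(matrix(0.5, 3, 3), gt))
  # exhaustive enumeration over all 9 peak positions
  set.seed(10)
  mask2 <- matrix(sample(c(TRUE, FALSE), 9, replace = TRUE), 3, 3)
  mask2[2, 2] <- TRUE
  gt2 <- new("GroundTruth", bbox = c(-1, -1, 1, 1),
             heatmap = mask2 * 1, mask = mask2, source = "box")
  for (i in 1:3) for (j in 1:3) {
    m <- matrix(0, 3, 3); m[i, j] <- 1
    expect_identical(pointingGame(m, gt2), mask2[i, j])
  }
  # invariant to strictly monotone rescaling
  m <- matrix(runif(9), 3, 3)
  expect_identical(pointingGame(m, gt2), pointingGame(m^3 + 2, gt2))
})

test_that("in/out means match a scalar loop and flag undefined ratios", {
  gt <- boxToMask(c(-1, -1, 0, 0), G = 5)
  expect_equal(inOutStats(matrix(0.4, 5, 5), gt)$ratio, 1)
  # map equal to the mask: infinite contrast is flagged, not fabricated
  s <- inOutStats(gt@mask * 1, gt)
  expect_equal(s$meanIn, 1)
  expect_equal(s$meanOut, 0)
  expect_true(is.na(s$ratio))
  # all-inside mask
  sAll <- inOutStats(matrix(0.5, 3, 3), boxToMask(c(-1, -1, 1, 1), G = 3))
  expect_true(is.na(sAll$ratio))
  # random maps against a double loop, 3 seeds
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(runif(25), 5, 5)
    s <- inOutStats(m, gt)
    si <- 0; so <- 0; ni <- 0; no <- 0
    for (i in 1:5) for (j in 1:5) {
      if (gt@mask[i, j]) { si <- si + m[i, j]; ni <- ni + 1 }
      else { so <- so + m[i, j]; no <- no + 1 }
    }
    expect_equal(s$meanIn, si / ni, tolerance = 1e-15)
    expect_equal(s$meanOut, so / no, tolerance = 1e-15)
    expect_equal(s$ratio, (si / ni) / (so / no), tolerance = 1e-12)
  }
})

test_that("IoU curves match set arithmetic and find their peak", {
  gt <- boxToMask(c(-1, -1, 0, 0), G = 11)
  # map identical to the mask: IoU 1 at any threshold in (0, 1]
  curve <- iouCurve(gt@mask * 1, gt, thresholds = c(0.25, 0.5, 1))
  expect_true(all(curve$iou == 1))
  # all-ones map: intersection = mask, union = whole grid
  gt40 <- boxToMask(c(-1, -1, 0.25, 0.25), G = 11)
  expect_equal(sum(gt40@mask), 49)
  c2 <- iouCurve(matrix(1, 11, 11), gt40, thresholds = 0.5)
  expect_equal(c2$iou, 49 / 121)
  # random maps against explicit set computation
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(runif(121), 11, 11)
    th <- seq(0, 1, length.out = 21)
    got <- iouCurve(m, gt, th)
    for (k in seq_along(th)) {
      bin <- which(m >= th[k])
      ms <- which(gt@mask)
      inter <- length(intersect(bin, ms))
      uni <- length(union(bin, ms))
      expect_equal(got$iou[k], if (uni == 0) 0 else inter / uni)
    }
    expect_equal(got$peakIoU, max(got$iou))
    expect_equal(got$peakThreshold, th[which.max(got$iou)])
  }
  expect_error(iouCurve(matrix(1, 3, 3), boxToMask(c(-1, -1, 1, 1), 3),
                        thresholds = 2), "thresholds")
  # symmetry in the two sets: swapping binarized map and mask leaves IoU
  # unchanged (IoU = 1 exactly when they coincide)
  ga <- boxToMask(c(-1, -1, 0, 0), G = 5)
  gb <- boxToMask(c(-0.4, -0.4, 1, 1), G = 5)
  expect_equal(iouCurve(ga@mask * 1, gb, thresholds = 0.5)$iou,
               iouCurve(gb@mask * 1, ga, thresholds = 0.5)$iou)
  expect_equal(iouCurve(ga@mask * 1, ga, thresholds = 0.5)$iou, 1)
})

test_that("dataset reports aggregate per-image scores", {
  gt <- boxToMask(c(-1, -1, 0, 0), G = 5)
  hit <- matrix(0, 5, 5); hit[2, 2] <- 1        # peak inside
  miss <- matrix(0, 5, 5); miss[5, 5] <- 1      # peak outside
  mk <- function(m) new("LikelihoodMap", values = m,
                        fixations = fixationGrid(5),
                        cropRadii = matrix(1, 5, 5), label = 1L,
                        mode = "cartesian")
  r1 <- datasetReport(list(mk(hit)), list(gt))
  expect_equal(r1$pointingRate, 1)
  r2 <- datasetReport(list(mk(hit), mk(miss)), list(gt, gt))
  expect_equal(r2$pointingRate, 0.5)
  expect_equal(r2$peakIoU, max(r2$iouCurve))
  expect_error(datasetReport(list(mk(hit)), list(gt, gt)), "align")
})
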