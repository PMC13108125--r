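test_that("the fixation grid spans the frame with the center at (0, 0)", {
  g1 <- fixationGrid(1)
  expect_equal(g1[1, 1, ], c(0, 0))
  g11 <- fixationGrid(11)
  expect_equal(g11[6, 6, ], c(0, 0))          # cell (5, 5) 0-based
  g3 <- fixationGrid(3)
  expect_equal(g3[1, 1, ], c(-1, -1))
  expect_equal(g3[3, 3, ], c(1, 1))
  expect_equal(g3[1, 3, ], c(1, -1))
  expect_error(fixationGrid(0), "G")
})

test_that("crop radius follows the distance-to-border rule with a 1:10 floor", {
  img <- generateTexture(1, imageSize = 64)
  expect_equal(cropAtFixation(img, c(0, 0))$radius, 1)
  expect_equal(cropAtFixation(img, c(1, 1))$radius, 0.1)
  expect_equal(cropAtFixation(img, c(0.5, 0))$radius, 0.5)
  expect_equal(cropAtFixation(img, c(-0.3, 0.9))$radius, 0.1)
  expect_error(cropAtFixation(img, c(1.2, 0)), "fixation")
  # central crop of a 64-raster at native resolution is the identity
  expect_equal(cropAtFixation(img, c(0, 0))$image@.Data, img@.Data,
               tolerance = 1e-12)
})

test_that("constant-output classifiers give constant maps", {
  q <- 0.3
  clf <- FunctionClassifier(function(imgs) {
    p <- matrix((1 - q) / 3, length(imgs), 4)
    p[, 2] <- q
    p
  }, nClasses = 4)
  img <- generateTexture(2, imageSize = 64)
  map <- likelihoodMap(clf, img, 2, G = 5)
  expect_true(all(mapValues(map) == q))
  expect_true(all(mapValues(map) >= 0 & mapValues(map) <= 1))
  expect_identical(dim(map@cropRadii), c(5L, 5L))
})

test_that("map cells equal independent per-fixation evaluations", {
  clf <- statClassifier()
  img <- generateTexture(3, imageSize = 64)
  G <- 5
  map <- likelihoodMap(clf, img, 1, G = G)
  fg <- fixationGrid(G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    cr <- cropAtFixation(img, fg[i, j, ], resolution = 64)
    p <- predictProbs(clf, cr$image)[1, ]
    expect_identical(mapValues(map)[i, j], p[1])
  }
})

test_that("multi-label maps slice one shared sweep", {
  clf <- statClassifier()
  img <- generateTexture(4, imageSize = 64)
  maps <- multiLabelMaps(clf, img, c(1, 3), G = 5)
  expect_identical(mapValues(maps[[1]]),
                   mapValues(likelihoodMap(clf, img, 1, G = 5)))
  allMaps <- multiLabelMaps(clf, img, 1:4, G = 5)
  total <- Reduce(`+`, lapply(allMaps, mapValues))
  expect_equal(max(abs(total - 1)), 0, tolerance = 1e-9)
  expect_error(multiLabelMaps(clf, img, c(2, 2), G = 3), "distinct")
})

test_that("saccade with G = 1 is central-fixation classification", {
  clf <- statClassifier()
  img <- generateTexture(5, imageSize = 64)
  s <- saccadeAndClassify(clf, img, 1, G = 1)
  expect_equal(s$fixation, c(0, 0))
  p0 <- predictProbs(clf, cropAtFixation(img, c(0, 0), resolution = 64)$image)[1, ]
  expect_identical(s$probs, p0)
})

test_that("recentering puts every peak at the canvas center", {
  mk <- function(m) new("LikelihoodMap", values = m,
                        fixations = fixationGrid(nrow(m)),
                        cropRadii = matrix(1, nrow(m), ncol(m)),
                        label = 1L, mode = "cartesian")
  # a map already peaked at the center: central window equals the map
  m1 <- matrix(0.1, 5, 5); m1[3, 3] <- 0.9
  agg1 <- recenterAndAggregate(list(mk(m1)))
  expect_equal(agg1@values[3:7, 3:7], m1)
  expect_true(all(is.na(agg1@values[1, ])))
  # aggregate central cell is the mean of the per-map maxima
  m2 <- matrix(0.2, 5, 5); m2[1, 4] <- 0.8
  agg <- recenterAndAggregate(list(mk(m1), mk(m2)))
  expect_equal(agg@values[5, 5], mean(c(0.9, 0.8)))
  # canvas maximum sits at the center cell
  expect_equal(which.max(agg@values), 5 + (5 - 1) * 9)
  expect_error(recenterAndAggregate(list()), "empty")
})

test_that("canvas coverage counts match a scalar enumeration", {
  G <- 4
  set.seed(6)
  maps <- lapply(1:7, function(k) {
    m <- matrix(runif(G * G), G, G)
    new("LikelihoodMap", values = m, fixations = fixationGrid(G),
        cropRadii = matrix(1, G, G), label = 1L, mode = "cartesian")
  })
  agg <- recenterAndAggregate(maps)
  counts <- matrix(0L, 2 * G - 1, 2 * G - 1)
  for (m in maps) {
    vals <- mapValues(m)
    # explicit row-major scan for the first maximizer
    peak <- NULL; pv <- -Inf
    for (i in seq_len(G)) for (j in seq_len(G))
      if (vals[i, j] > pv) { pv <- vals[i, j]; peak <- c(i, j) }
    for (i in seq_len(G)) for (j in seq_len(G))
      counts[i - peak[1] + G, j - peak[2] + G] <-
        counts[i - peak[1] + G, j - peak[2] + G] + 1L
  }
  expect_identical(agg@counts, counts)
})

test_that("map algebra: differences, log-odds, and clamping", {
  mk <- function(v) new("AggregateMaps",
                        values = matrix(v, 3, 3),
                        counts = matrix(1L, 3, 3))
  a <- mk(0.5); b <- mk(0.2)
  out <- mapAlgebra(a, a)
  expect_true(all(out$difference == 0))
  expect_true(all(out$logOdds == 0))
  out2 <- mapAlgebra(a, b)
  expect_equal(out2$difference[1, 1], 0.3)
  expect_equal(out2$logOdds[1, 1], -log(0.2 / 0.8))   # logit(0.5) = 0
  clamped <- mapAlgebra(mk(1), mk(0.5))
  expect_equal(clamped$logOdds[1, 1], log((1 - 1e-6) / 1e-6),
               tolerance = 1e-9)
  expect_equal(clamped$logOdds[1, 1], 13.8155, tolerance = 1e-3)
  big <- new("AggregateMaps", values = matrix(0.5, 5, 5),
             counts = matrix(1L, 5, 5))
  expect_error(mapAlgebra(a, big), "shape")
})

test_that("undefined cells propagate through map algebra", {
  v <- matrix(0.4, 3, 3); v[1, 1] <- NA
  cnt <- matrix(1L, 3, 3); cnt[1, 1] <- 0L
  a <- new("AggregateMaps", values = v, counts = cnt)
  b <- new("AggregateMaps", values = matrix(0.4, 3, 3),
           counts = matrix(1L, 3, 3))
  out <- mapAlgebra(a, b)
  expect_true(is.na(out$difference[1, 1]))
  expect_true(is.na(out$logOdds[1, 1]))
  expect_equal(out$difference[2, 2], 0)
})
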