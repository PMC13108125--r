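test_that("grid construction hits the documented endpoints and geometry", {
  g <- buildGrid(FoveationConfig())
  expect_lt(abs(g@rho[1] - 2^-5), 1e-12)
  expect_lt(abs(g@rho[224] - 1), 1e-12)
  # log2 of the radii is uniformly spaced
  expect_lt(max(abs(diff(log2(g@rho)) - 5 / 223)), 1e-12)
  # outer ring, azimuth 0: the point (1, 0) tangent to the image box
  expect_equal(g@coords[224, 1, ], c(1, 0), tolerance = 1e-12)
  # innermost ring, azimuth 0
  expect_equal(g@coords[1, 1, ], c(2^-5, 0), tolerance = 1e-12)
  # azimuth covers [0, 2*pi): periodic continuation wraps exactly
  expect_equal(g@theta, (0:223) * 2 * pi / 224)
  expect_equal(g@coords[, 1, ],
               buildGrid(FoveationConfig())@coords[, (224 %% 224) + 1, ])
  # moved fixation: outer ring at theta = pi lands at fixation - (rmax, 0)
  gf <- buildGrid(FoveationConfig(nTheta = 4, nRho = 8,
                                  fixation = c(0.5, 0.5)))
  expect_equal(gf@coords[8, 3, ], c(-0.5, 0.5), tolerance = 1e-12)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(FoveationConfig(nTheta = 1), "nTheta")
  expect_error(FoveationConfig(nRho = 0), "nRho")
  expect_error(FoveationConfig(log2RMin = 0, log2RMax = 0), "log2RMin")
  expect_error(FoveationConfig(fixation = c(2, 0)), "fixation")
  expect_error(FoveationConfig(log2RMin = NaN), "log2RMin")
})

test_that("forward transform equals the scalar bilinear oracle exactly", {
  cfg <- FoveationConfig(nTheta = 24, nRho = 20, fixation = c(0.1, -0.2))
  for (seed in 1:3) {
    set.seed(seed)
    mat <- matrix(runif(16 * 16), 16, 16)
    lp <- toLogPolar(ImageRaster(mat), cfg)
    oracle <- oracleLogPolar(mat, 24, 20, fixation = c(0.1, -0.2))
    expect_equal(mapValues(lp)[1, , ], oracle, tolerance = 1e-14)
  }
})

test_that("a constant image stays constant through both transforms", {
  cfg <- FoveationConfig(nTheta = 48, nRho = 40)
  lp <- toLogPolar(matrix(0.7, 32, 32), cfg)
  expect_equal(max(abs(mapValues(lp) - 0.7)), 0, tolerance = 1e-12)
  rec <- fromLogPolar(lp, 32, 32)
  pc <- FoveatedVision:::.pixelCenters(32, 32)
  r <- sqrt(outer(pc$y^2, pc$x^2, `+`))
  expect_equal(max(abs(rec[1, , ][r <= 1] - 0.7)), 0, tolerance = 1e-12)
  # pixels beyond the outer radius take the fill value
  expect_true(all(rec[1, , ][r > 1.05] == 0))
})

test_that("default 224-grid maps a 224 x 224 raster to the same spatial shape", {
  img <- generateTexture(3, imageSize = 224)
  lp <- toLogPolar(img, FoveationConfig())
  expect_identical(dim(lp), c(1L, 224L, 224L))
})

test_that("horizontal gradients map to the analytic expression", {
  # I(x, y) = (x + 1)/2 sampled anywhere in frame gives back (x + 1)/2,
  # up to the pixel-center discretization of the source grid
  cfg <- FoveationConfig(nTheta = 64, nRho = 64)
  N <- 128
  pc <- FoveatedVision:::.pixelCenters(N, N)
  img <- matrix(rep((pc$x + 1) / 2, each = N), N, N)
  lp <- toLogPolar(ImageRaster(img), cfg)
  g <- buildGrid(cfg)
  expected <- (g@coords[, , 1] + 1) / 2
  # interior of a linear ramp is reproduced exactly; border clamping keeps
  # samples within half a pixel of the analytic value
  expect_lt(max(abs(mapValues(lp)[1, , ] - expected)), 1 / N)
})

test_that("locality: one changed source pixel only moves nearby samples", {
  cfg <- FoveationConfig(nTheta = 32, nRho = 32)
  set.seed(7)
  mat <- matrix(runif(16 * 16), 16, 16)
  mat2 <- mat
  mat2[9, 12] <- mat2[9, 12] + 0.5
  d <- abs(mapValues(toLogPolar(mat2, cfg)) - mapValues(toLogPolar(mat, cfg)))
  changed <- which(d[1, , ] > 1e-14, arr.ind = TRUE)
  g <- buildGrid(cfg)
  # source pixel center of (9, 12) in normalized units; one pixel = 2/16
  px <- (2 * 12 - 1) / 16 - 1
  py <- (2 * 9 - 1) / 16 - 1
  for (k in seq_len(nrow(changed))) {
    co <- g@coords[changed[k, 1], changed[k, 2], ]
    expect_lt(max(abs(co - c(px, py))), 2 / 16 + 1e-12)
  }
})

test_that("reconstruction error grows with eccentricity on a smooth image", {
  img <- generateTexture(5, imageSize = 64)
  cfg <- FoveationConfig(nTheta = 64, nRho = 64)
  rec <- fromLogPolar(toLogPolar(img, cfg), 64, 64)
  pc <- FoveatedVision:::.pixelCenters(64, 64)
  r <- sqrt(outer(pc$y^2, pc$x^2, `+`))
  err <- abs(rec[1, , ] - img[1, , ])
  # mean abs error per eccentricity band, fovea outward; the innermost
  # log-spaced bands can be empty of pixel centers and are dropped
  edges <- 2^seq(-5, 0, length.out = 13)
  ringErr <- vapply(seq_len(length(edges) - 1), function(k)
    mean(err[r >= edges[k] & r < edges[k + 1]]), numeric(1))
  idx <- which(is.finite(ringErr))
  expect_gt(length(idx), 5)
  expect_gt(cor(idx, ringErr[idx], method = "spearman"), 0)
})

test_that("circular mask keeps the disk and fills the corners", {
  img <- matrix(0.6, 100, 100)
  expect_equal(circularMask(img, radius = sqrt(2))@.Data[1, , ], img)
  masked <- circularMask(img, radius = 1)
  frac <- mean(masked[1, , ] == 0)
  expect_lt(abs(frac - (1 - pi / 4)), 0.01)
  expect_true(all(masked[1, , ] %in% c(0, 0.6)))
  # degenerate limit: a vanishing radius keeps (at most) the fixation pixel
  tiny <- circularMask(img, radius = 1e-6)
  expect_lte(sum(tiny[1, , ] != 0), 1)
  expect_error(circularMask(img, radius = 0), "radius")
})

test_that("non-square rasters use per-axis normalized coordinates", {
  set.seed(9)
  mat <- matrix(runif(12 * 30), 12, 30)
  cfg <- FoveationConfig(nTheta = 16, nRho = 12)
  lp <- toLogPolar(mat, cfg)
  oracle <- oracleLogPolar(mat, 16, 12)
  expect_equal(mapValues(lp)[1, , ], oracle, tolerance = 1e-14)
})
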