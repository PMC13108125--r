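# The convolution stack and its training machinery. Heavy end-to-end
# training quality is exercised in the acceptance suite through the shared
# model cache; here the mechanics are checked cheaply.

test_that("the im2col convolution matches a direct convolution loop", {
  ix <- FoveatedVision:::.convIndex(8L, 8L, 1L, 3L, 3L, stride = 2L,
                                    padH = 1L, padW = 1L, circularW = FALSE)
  set.seed(4)
  x <- matrix(runif(64), 8, 8)
  W <- matrix(rnorm(2 * 9), 2, 9)
  col <- matrix(c(as.vector(x), 0)[ix$idx], ix$k, ix$P)
  got <- W %*% col                       # 2 x 16, columns in (io, jo) order
  for (io in 1:4) for (jo in 1:4) {
    patch <- numeric(9)
    k <- 0
    for (kj in 1:3) for (ki in 1:3) {    # ki fastest, then kj (ch = 1)
      k <- k + 1
      i <- (io - 1) * 2 + ki - 1
      j <- (jo - 1) * 2 + kj - 1
      patch[k] <- if (i >= 1 && i <= 8 && j >= 1 && j <= 8) x[i, j] else 0
    }
    expect_equal(got[, io + (jo - 1) * 4], as.vector(W %*% patch),
                 tolerance = 1e-12)
  }
})

test_that("circular azimuth padding wraps instead of zero-filling", {
  ix <- FoveatedVision:::.convIndex(4L, 4L, 1L, 3L, 3L, stride = 1L,
                                    padH = 1L, padW = 1L, circularW = TRUE)
  x <- matrix(1:16, 4, 4)
  col <- matrix(c(as.vector(x), 0)[ix$idx], ix$k, ix$P)
  # output position (2, 1): the kernel's left column samples source column 4
  patch <- col[, 2 + (1 - 1) * 4]
  expect_true(all(patch[1:3] == x[1:3, 4]))
  # vertical padding is still zero
  top <- col[, 1 + (1 - 1) * 4]
  expect_identical(top[1], 0)
})

test_that("batched training gradients equal per-image gradients summed", {
  net <- FoveatedVision:::.toyNetInit(c(32L, 32L), 3L, FALSE, seed = 5)
  set.seed(2)
  Xs <- matrix(runif(32 * 32 * 5), ncol = 5)
  labels <- c(1L, 3L, 2L, 2L, 1L)
  gb <- FoveatedVision:::.toyBatchGrad(net, Xs, labels)
  ref <- NULL
  for (i in 1:5) {
    fwd <- FoveatedVision:::.toyForward(net, Xs[, i], keep = TRUE)
    g <- FoveatedVision:::.toyBackward(net, Xs[, i], fwd, labels[i])
    if (is.null(ref)) ref <- g else {
      ref$V <- ref$V + g$V; ref$c <- ref$c + g$c
      for (li in seq_along(ref$layers)) {
        ref$layers[[li]]$W <- ref$layers[[li]]$W + g$layers[[li]]$W
        ref$layers[[li]]$b <- ref$layers[[li]]$b + g$layers[[li]]$b
      }
    }
  }
  expect_equal(gb$V, ref$V, tolerance = 1e-12)
  expect_equal(gb$c, ref$c, tolerance = 1e-12)
  for (li in seq_along(ref$layers)) {
    expect_equal(gb$layers[[li]]$W, ref$layers[[li]]$W, tolerance = 1e-12)
    expect_equal(gb$layers[[li]]$b, ref$layers[[li]]$b, tolerance = 1e-12)
  }
})

test_that("analytic gradients match numerical differentiation", {
  net <- FoveatedVision:::.toyNetInit(c(16L, 16L), 3L, TRUE, seed = 5)
  set.seed(2)
  x <- runif(16 * 16)
  label <- 2L
  fwd <- FoveatedVision:::.toyForward(net, x, keep = TRUE)
  g <- FoveatedVision:::.toyBackward(net, x, fwd, label)
  lossAt <- function(n) -log(FoveatedVision:::.toyForward(n, x)[label])
  eps <- 1e-6
  set.seed(3)
  for (li in 1:2) {
    i <- sample(length(net$layers[[li]]$W), 1)
    np <- net; np$layers[[li]]$W[i] <- np$layers[[li]]$W[i] + eps
    nm <- net; nm$layers[[li]]$W[i] <- nm$layers[[li]]$W[i] - eps
    num <- (lossAt(np) - lossAt(nm)) / (2 * eps)
    expect_equal(g$layers[[li]]$W[i], num, tolerance = 1e-5)
  }
  i <- sample(length(net$V), 1)
  np <- net; np$V[i] <- np$V[i] + eps
  nm <- net; nm$V[i] <- nm$V[i] - eps
  expect_equal(g$V[i], (lossAt(np) - lossAt(nm)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("predictions are bitwise independent of batch composition", {
  clf <- untrainedToy("retinotopic")
  imgs <- lapply(1:4, function(s) generateTexture(s, imageSize = 64))
  pAll <- predictProbs(clf, imgs)
  for (i in 1:4)
    expect_identical(pAll[i, ], predictProbs(clf, imgs[[i]])[1, ])
})

test_that("an untrained classifier sits at chance level", {
  clf <- untrainedToy("cartesian")
  test <- makeFixtureBenchmark(120, seed = 77)$regular
  acc <- classifierAccuracy(clf, test)
  # binomial 99.9% band around 1/4 for n = 120
  expect_lt(abs(acc - 0.25), 3.3 * sqrt(0.25 * 0.75 / 120))
  p <- predictProbs(clf, test@images[1:5])
  expect_true(all(p >= 0))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
})

test_that("training is reproducible given the seed and validates inputs", {
  small <- makeFixtureBenchmark(24, seed = 5)$regular
  a <- trainToyClassifier(small, "cartesian", epochs = 2, seed = 9,
                          restarts = 0, restartThreshold = 0)
  b <- trainToyClassifier(small, "cartesian", epochs = 2, seed = 9,
                          restarts = 0, restartThreshold = 0)
  expect_identical(a@net, b@net)
  expect_error(trainToyClassifier(small, "cartesian", epochs = 0), "epochs")
})
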