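## A small convolutional classifier harness, written in base R.
##
## Architecture (for a 64 x 64 single-channel input): a 7x7, 24-channel,
## stride-4 convolution stem and a 5x5, 48-channel, stride-2 convolution
## (each followed by ReLU), global average pooling, and a linear softmax
## head. The wide stride-4 stem keeps the computation small enough that the
## whole harness trains in well under a minute on one CPU while converging
## reliably under plain SGD with momentum. Convolutions are evaluated by
## im2col gathers (a precomputed index vector into the padded input) followed
## by one matrix product, so training and inference stay fast on one CPU
## without any external NN library. In retinotopic mode the padding along the
## azimuth (column) axis is circular, matching the periodic topology of the
## log-polar raster; everywhere else it is zero padding.
##
## Inference always processes images one at a time through identical
## operations, so predictions are bit-for-bit independent of how a batch is
## composed — the attack and likelihood-map code relies on this.

## Precompute the combined pad + im2col gather index for one conv layer.
## Index nAug = H*W*Cin + 1 points at an appended zero (zero padding);
## circularW wraps the column axis instead.
.convIndex <- function(H, W, Cin, kh, kw, stride, padH, padW, circularW) {
  Ho <- (H + 2L * padH - kh) %/% stride + 1L
  Wo <- (W + 2L * padW - kw) %/% stride + 1L
  g <- expand.grid(ki = seq_len(kh), kj = seq_len(kw), ch = seq_len(Cin),
                   io = seq_len(Ho), jo = seq_len(Wo))
  i <- (g$io - 1L) * stride + g$ki - padH
  j <- (g$jo - 1L) * stride + g$kj - padW
  if (circularW) j <- ((j - 1L) %% W) + 1L
  valid <- i >= 1L & i <= H & j >= 1L & j <= W
  nAug <- H * W * Cin + 1L
  idx <- ifelse(valid, i + (j - 1L) * H + (g$ch - 1L) * H * W, nAug)
  list(idx = as.integer(idx), k = kh * kw * Cin, P = Ho * Wo,
       Ho = Ho, Wo = Wo, nAug = nAug)
}

## Build the network skeleton (index tables and zero-initialized weights).
.toyNetInit <- function(res, nClasses, circularW, seed) {
  spec <- list(list(kh = 7L, kw = 7L, cout = 24L, pad = 3L, stride = 4L),
               list(kh = 5L, kw = 5L, cout = 48L, pad = 2L, stride = 2L))
  layers <- list()
  H <- res[1]; W <- res[2]; Cin <- 1L
  .withSeed(seed, {
    for (s in spec) {
      ix <- .convIndex(H, W, Cin, s$kh, s$kw, stride = s$stride,
                       padH = s$pad, padW = s$pad, circularW = circularW)
      layers[[length(layers) + 1L]] <- list(
        W = matrix(rnorm(s$cout * ix$k, sd = sqrt(2 / ix$k)), s$cout, ix$k),
        b = numeric(s$cout), idx = ix$idx, k = ix$k, P = ix$P,
        Ho = ix$Ho, Wo = ix$Wo, cin = Cin, hin = H, win = W, nAug = ix$nAug)
      H <- ix$Ho; W <- ix$Wo; Cin <- s$cout
    }
    list(layers = layers,
         V = matrix(rnorm(nClasses * Cin, sd = sqrt(2 / Cin)), nClasses, Cin),
         c = numeric(nClasses))
  })
}

## Forward pass for one image (x: H*W vector). Returns activations when
## keep = TRUE (training), otherwise just the probability vector.
.toyForward <- function(net, x, keep = FALSE) {
  acts <- if (keep) vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    col <- matrix(c(x, 0)[l$idx], l$k, l$P)
    z <- l$W %*% col + l$b
    a <- z * (z > 0)
    if (keep) acts[[li]] <- list(col = col, pos = z > 0, a = a)
    x <- as.vector(t(a))               # layout (Ho, Wo, Cout) for next layer
  }
  lastP <- net$layers[[length(net$layers)]]$P
  feat <- if (keep) rowMeans(acts[[length(acts)]]$a)
          else colMeans(matrix(x, lastP, length(x) / lastP))
  logits <- as.vector(net$V %*% feat + net$c)
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  if (keep) list(p = p, feat = feat, acts = acts) else p
}

## Batched forward + gradient over a minibatch (training only; inference
## stays strictly per-image). Xs is a (H*W) x B matrix of preprocessed
## inputs; returns the summed gradient and the batch loss.
.toyBatchGrad <- function(net, Xs, labels) {
  B <- ncol(Xs)
  X <- Xs
  store <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    Xa <- rbind(X, 0)
    col <- Xa[l$idx, , drop = FALSE]           # (k*P) x B
    dim(col) <- c(l$k, l$P * B)
    z <- l$W %*% col + l$b
    a <- z * (z > 0)
    store[[li]] <- list(col = col, pos = z > 0)
    cout <- nrow(l$W)
    dim(a) <- c(cout, l$P, B)
    a <- aperm(a, c(2, 1, 3))                  # (P, Cout, B)
    dim(a) <- c(l$P * cout, B)
    X <- a
    store[[li]]$a <- a
  }
  lastL <- net$layers[[length(net$layers)]]
  coutL <- nrow(lastL$W)
  fm <- X
  dim(fm) <- c(lastL$P, coutL * B)
  featM <- matrix(colMeans(fm), coutL, B)
  logits <- net$V %*% featM + net$c
  logits <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(logits)
  p <- sweep(e, 2, colSums(e), `/`)
  loss <- mean(-log(pmax(p[cbind(labels, seq_len(B))], 1e-12)))

  dLogit <- p
  dLogit[cbind(labels, seq_len(B))] <- dLogit[cbind(labels, seq_len(B))] - 1
  g <- list(V = dLogit %*% t(featM), c = rowSums(dLogit), layers = list())
  dFeat <- crossprod(net$V, dLogit)            # Cout x B
  dA <- dFeat[, rep(seq_len(B), each = lastL$P), drop = FALSE] / lastL$P
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    st <- store[[li]]
    dZ <- dA * st$pos
    g$layers[[li]] <- list(W = dZ %*% t(st$col), b = rowSums(dZ))
    dCol <- crossprod(l$W, dZ)                 # k x (P*B)
    dim(dCol) <- c(l$k * l$P, B)
    acc <- rowsum(dCol, group = l$idx)
    dXa <- matrix(0, l$nAug, B)
    dXa[as.integer(rownames(acc)), ] <- acc
    if (li > 1L) {
      prev <- net$layers[[li - 1L]]
      coutP <- nrow(prev$W)
      dX <- dXa[-l$nAug, , drop = FALSE]       # (P_prev*C_prev) x B
      dim(dX) <- c(prev$P, coutP, B)
      dX <- aperm(dX, c(2, 1, 3))
      dim(dX) <- c(coutP, prev$P * B)
      dA <- dX
    }
  }
  g$loss <- loss
  g
}

## Gradient of the cross-entropy loss for one image; returns a list matching
## the weight structure.
.toyBackward <- function(net, x, fwd, label) {
  dLogit <- fwd$p
  dLogit[label] <- dLogit[label] - 1
  g <- list(V = dLogit %o% fwd$feat, c = dLogit, layers = list())
  nl <- length(net$layers)
  dFeat <- as.vector(crossprod(net$V, dLogit))
  l <- net$layers[[nl]]
  dA <- matrix(dFeat / l$P, length(dFeat), l$P)
  for (li in rev(seq_len(nl))) {
    l <- net$layers[[li]]
    act <- fwd$acts[[li]]
    dZ <- dA * act$pos
    g$layers[[li]] <- list(W = dZ %*% t(act$col), b = rowSums(dZ))
    dCol <- crossprod(l$W, dZ)          # k x P
    acc <- rowsum(as.vector(dCol), group = l$idx)
    dx <- numeric(l$nAug)
    dx[as.integer(rownames(acc))] <- acc
    if (li > 1L) {
      prev <- net$layers[[li - 1L]]
      # dx (without the pad slot) has layout (Ho, Wo, Cout) of layer li - 1
      dv <- dx[-l$nAug]
      dA <- t(matrix(dv, prev$P, length(dv) / prev$P))
    }
  }
  g
}

#' Trained small convolutional classifier
#'
#' Produced by [trainToyClassifier()]. Satisfies the [predictProbs()]
#' contract; `inputMode()` reports whether the classifier consumes
#' circular-masked Cartesian rasters or log-polar transformed rasters.
#' Prediction applies the mode's preprocessing internally, so callers always
#' supply Cartesian images (perturb -> foveate -> classify).
#'
#' @slot net list of convolution layers and the linear head.
#' @slot config the [FoveationConfig-class] used for retinotopic
#'   preprocessing.
#' @slot classNames class names, one per output unit.
#' @export
setClass("ToyClassifier", contains = "Classifier",
         representation(net = "list", config = "FoveationConfig",
                        classNames = "character"))

## mode preprocessing: resize -> circular mask (cartesian) or log-polar
## (retinotopic); multi-channel inputs are averaged to one luminance channel.
.toyPreprocess <- function(object, arr) {
  arr <- .rasterArray(arr)
  if (dim(arr)[1] > 1L)
    arr <- array(colMeans(matrix(arr, dim(arr)[1])), c(1L, dim(arr)[2], dim(arr)[3]))
  arr <- .resampleTo(arr, object@resolution[1], object@resolution[2])
  m <- if (object@mode == "cartesian")
    .maskArray(arr, radius = 1)[1, , ]
  else
    .logPolarArray(arr, object@config)[1, , ]
  as.vector(m - 0.5) * 2            # center [0,1] pixel values to [-1, 1]
}

#' @describeIn ToyClassifier-class Predict class probabilities. Images are
#'   processed strictly one at a time, so results do not depend on batch
#'   composition.
#' @param object a `ToyClassifier`.
#' @param images list of image rasters (or a single raster).
#' @export
setMethod("predictProbs", "ToyClassifier", function(object, images) {
  images <- .imageBatch(images)
  p <- t(vapply(images,
                function(im) .toyForward(object@net, .toyPreprocess(object, im)),
                numeric(object@nClasses)))
  colnames(p) <- object@classNames
  checkProbabilityContract(p)
  p
})

#' Train the toy convolutional classifier on fixture data
#'
#' Trains the three-block CNN with plain stochastic gradient descent with
#' momentum on the cross-entropy loss. In `"retinotopic"` mode every training
#' image is first log-polar transformed (at the classifier's input
#' resolution) and the convolutions pad circularly along the azimuth axis; in
#' `"cartesian"` mode images are circular-masked and padding is zero.
#' Preprocessed inputs are cached once, so epochs are cheap.
#'
#' Training is reproducible: weight initialization and example shuffling are
#' driven by `seed` alone.
#'
#' @param data a [FixtureDataset-class], or a list of them (concatenated, e.g.
#'   the regular and focus variants together).
#' @param mode `"cartesian"` or `"retinotopic"`.
#' @param epochs number of passes over the data (>= 1).
#' @param seed integer RNG seed.
#' @param resolution square input resolution (default 64).
#' @param lr,momentum,batchSize SGD hyper-parameters. The learning rate is
#'   larger than typical fine-tuning rates because the toy net trains from
#'   scratch on easy synthetic classes.
#' @param backgroundClass when `TRUE` (the default) an extra `"background"`
#'   output class is trained on object-free crops taken from the same
#'   scenes. The photographic datasets this harness emulates are full of
#'   object-free views, and without them the net assigns confident object
#'   labels to featureless patches, corrupting fixation likelihood maps at
#'   small border crops.
#' @param restarts plain SGD from a random initialization occasionally lands
#'   in a poor basin; if the final training-set accuracy falls below
#'   `restartThreshold`, training restarts from a deterministically shifted
#'   seed, at most this many times.
#' @param restartThreshold training-set accuracy below which a restart is
#'   triggered.
#' @return a [ToyClassifier-class].
#' @export
trainToyClassifier <- function(data, mode = c("cartesian", "retinotopic"),
                               epochs = 18L, seed = 1L, resolution = 64L,
                               lr = 0.08, momentum = 0.9, batchSize = 40L,
                               backgroundClass = TRUE, restarts = 2L,
                               restartThreshold = 0.9) {
  mode <- match.arg(mode)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (is(data, "FixtureDataset")) data <- list(data)
  images <- do.call(c, lapply(data, function(d) d@images))
  labels <- do.call(c, lapply(data, function(d) d@labels))
  classNames <- data[[1L]]@classNames
  if (length(images) == 0L) stop("dataset is empty")
  if (backgroundClass) {
    bg <- .backgroundCrops(data, seed)
    if (length(bg) > 0L) {
      classNames <- c(classNames, "background")
      images <- c(images, bg)
      labels <- c(labels, rep(length(classNames), length(bg)))
    }
  }
  res <- as.integer(c(resolution, resolution))
  cfg <- FoveationConfig(nTheta = res[2], nRho = res[1])
  clf <- new("ToyClassifier", mode = mode, resolution = res,
             nClasses = length(classNames), classNames = classNames,
             net = list(),
             config = cfg)
  Xs <- vapply(images, function(im) .toyPreprocess(clf, im),
               numeric(prod(res)))
  n <- ncol(Xs)

  best <- NULL
  bestAcc <- -1
  for (attempt in 0:max(0L, restarts)) {
    attemptSeed <- seed + 1009L * attempt
    net <- .toyNetInit(res, length(classNames),
                       circularW = (mode == "retinotopic"),
                       seed = attemptSeed)
    vel <- rapply(net, function(w) w * 0, how = "replace")
    .withSeed(attemptSeed + 1L, {
      for (ep in seq_len(epochs)) {
        # step decay: full rate for 60% of epochs, then 0.3x, then 0.1x
        lrEp <- lr * if (ep <= 0.6 * epochs) 1 else if (ep <= 0.85 * epochs) 0.3 else 0.1
        ord <- sample.int(n)
        for (start in seq(1L, n, by = batchSize)) {
          batch <- ord[start:min(start + batchSize - 1L, n)]
          grad <- .toyBatchGrad(net, Xs[, batch, drop = FALSE], labels[batch])
          scale <- 1 / length(batch)
          vel$V <- momentum * vel$V - lrEp * scale * grad$V
          net$V <- net$V + vel$V
          vel$c <- momentum * vel$c - lrEp * scale * grad$c
          net$c <- net$c + vel$c
          for (li in seq_along(net$layers)) {
            vel$layers[[li]]$W <- momentum * vel$layers[[li]]$W -
              lrEp * scale * grad$layers[[li]]$W
            net$layers[[li]]$W <- net$layers[[li]]$W + vel$layers[[li]]$W
            vel$layers[[li]]$b <- momentum * vel$layers[[li]]$b -
              lrEp * scale * grad$layers[[li]]$b
            net$layers[[li]]$b <- net$layers[[li]]$b + vel$layers[[li]]$b
          }
        }
      }
    })
    trainAcc <- mean(vapply(seq_len(n), function(i)
      which.max(.toyForward(net, Xs[, i])), integer(1)) == labels)
    if (trainAcc > bestAcc) {
      best <- net
      bestAcc <- trainAcc
    }
    if (trainAcc >= restartThreshold) break
  }
  clf@net <- best
  clf
}

## Object-free views for the optional background class: for every scene,
## pick (seeded) one fixation of the standard 11 x 11 grid whose crop square
## does not intersect the object's bounding box, and take that crop.
.backgroundCrops <- function(data, seed) {
  crops <- list()
  fg <- fixationGrid(11L)
  pts <- cbind(as.vector(fg[, , 1]), as.vector(fg[, , 2]))
  .withSeed(seed + 2L, {
    for (d in data) {
      if (d@variant != "regular") next
      for (i in seq_len(length(d))) {
        bb <- d@bboxes[i, ]
        r <- pmax(pmin(1 - abs(pts[, 1]), 1 - abs(pts[, 2])), 0.1)
        ok <- pts[, 1] + r < bb[1] | pts[, 1] - r > bb[3] |
              pts[, 2] + r < bb[2] | pts[, 2] - r > bb[4]
        if (!any(ok)) next
        k <- sample(which(ok), 1L)
        crops[[length(crops) + 1L]] <-
          cropAtFixation(d@images[[i]], pts[k, ])$image
      }
    }
  })
  crops
}

#' Top-1 accuracy of a classifier on a fixture dataset
#'
#' @param clf a classifier satisfying the [predictProbs()] contract.
#' @param data a [FixtureDataset-class].
#' @return fraction of correctly classified scenes.
#' @export
classifierAccuracy <- function(clf, data) {
  p <- predictProbs(clf, data@images)
  mean(max.col(p, ties.method = "first") == data@labels)
}
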