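## Shared bilinear resampling core. Every geometric operation in the package
## (forward/inverse log-polar mapping, rotation, zoom, cropping, resizing)
## funnels through .bilinearSample so one interpolation rule holds everywhere:
##
##  * normalized coordinates strictly outside [-1, 1]^2 receive the fill value;
##  * coordinates inside the frame are clamped to the border pixel centers
##    (border replication), so a constant image stays exactly constant under
##    any in-frame resampling;
##  * otherwise plain bilinear interpolation of the four neighbouring pixel
##    centers, with pixel center c (1-based column) at x = (2c - 1)/W - 1.

## img: channels x H x W array; x, y numeric vectors of equal length.
## Returns a channels x length(x) matrix.
.bilinearSample <- function(img, x, y, fill = 0) {
  d <- dim(img)
  C <- d[1]; H <- d[2]; W <- d[3]
  out <- !(x >= -1 & x <= 1 & y >= -1 & y <= 1)   # strictly outside the frame

  # continuous 1-based pixel coordinates of the sample
  jc <- (x + 1) * (W / 2) + 0.5
  ic <- (y + 1) * (H / 2) + 0.5
  jc[jc < 1] <- 1; jc[jc > W] <- W
  ic[ic < 1] <- 1; ic[ic > H] <- H
  j0 <- floor(jc); j0[j0 > W - 1] <- W - 1; wx <- jc - j0
  i0 <- floor(ic); i0[i0 > H - 1] <- H - 1; wy <- ic - i0

  idx00 <- i0 + (j0 - 1) * H
  if (C == 1L) {
    flat <- as.vector(img)
    v <- flat[idx00]      * ((1 - wx) * (1 - wy)) +
         flat[idx00 + H]  * (wx * (1 - wy)) +
         flat[idx00 + 1]  * ((1 - wx) * wy) +
         flat[idx00 + H + 1] * (wx * wy)
    if (any(out)) v[out] <- fill
    return(matrix(v, 1L))
  }
  flat <- img
  dim(flat) <- c(C, H * W)
  v <- flat[, idx00, drop = FALSE]           * rep((1 - wx) * (1 - wy), each = C) +
       flat[, idx00 + H, drop = FALSE]       * rep(wx * (1 - wy), each = C) +
       flat[, idx00 + 1L, drop = FALSE]      * rep((1 - wx) * wy, each = C) +
       flat[, idx00 + H + 1L, drop = FALSE]  * rep(wx * wy, each = C)
  if (any(out)) v[, out] <- fill
  v
}

## sample coordinates of every output pixel center, row index varying fastest
## (matches expand.grid(y, x) ordering used throughout)
.gridXY <- function(H, W) {
  pc <- .pixelCenters(H, W)
  list(x = rep(pc$x, each = H), y = rep.int(pc$y, W))
}

## Normalized pixel-center coordinates of an H x W raster.
.pixelCenters <- function(H, W) {
  list(x = (2 * seq_len(W) - 1) / W - 1,
       y = (2 * seq_len(H) - 1) / H - 1)
}

## Resample an image to a new resolution by bilinear interpolation at the
## target pixel centers. Identity resolutions return the input untouched.
.resampleTo <- function(img, H, W, fill = 0) {
  d <- dim(img)
  if (d[2] == H && d[3] == W) return(img)
  xy <- .gridXY(H, W)
  v <- .bilinearSample(img, xy$x, xy$y, fill = fill)
  array(v, c(d[1], H, W))
}

#' Resize an image raster
#'
#' Bilinear resampling at the target pixel centers, under the same
#' interpolation rule as the log-polar transform. A no-op when the target
#' resolution equals the source.
#'
#' @param image an `ImageRaster`, channels x H x W array, or matrix.
#' @param height,width target resolution (>= 2).
#' @param fill value for samples outside the source frame (only reachable for
#'   degenerate inputs; kept for symmetry with the other resamplers).
#' @return an [ImageRaster].
#' @export
resizeImage <- function(image, height, width, fill = 0) {
  if (height < 2 || width < 2) stop("target dimensions must be >= 2")
  ImageRaster(.resampleTo(.rasterArray(image), as.integer(height),
                          as.integer(width), fill = fill))
}

## Evaluate expr with a temporarily fixed RNG seed, restoring state after.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
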