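## Forward (Cartesian -> log-polar) and inverse (log-polar -> Cartesian)
## retinotopic resampling with a movable fixation point.
##
## The sampled eccentricities form a geometric progression: log2(rho) is
## uniform on [log2RMin, log2RMax], i.e. rho_i = rmin * (rmax/rmin)^(i/(N-1)).
## This spacing is what turns uniform zooms about the fixation point into row
## shifts of the log-polar raster; azimuths are uniform on [0, 2*pi), which
## turns rotations into circular column shifts. The fixation point itself
## (rho = 0) is never on the grid since rho_1 = rmin > 0.

.gridCache <- new.env(parent = emptyenv())

#' Build the log-polar sampling grid
#'
#' Computes, for every (eccentricity ring i, azimuth j) sample, the Cartesian
#' source coordinate `(x0 + rho_i * cos(theta_j), y0 + rho_i * sin(theta_j))`
#' in normalized units. With the default configuration the innermost ring has
#' radius 2^-5 and the outermost radius 1, a circle tangent to the image box.
#'
#' @param config a [FoveationConfig-class].
#' @return a [SamplingGrid-class].
#' @examples
#' g <- buildGrid(FoveationConfig())
#' g@coords[224, 1, ]   # outer ring at azimuth 0: (1, 0)
#' @export
buildGrid <- function(config) {
  stopifnot(is(config, "FoveationConfig"))
  validObject(config)
  key <- paste(config@nTheta, config@nRho, config@log2RMin, config@log2RMax,
               config@fixation[1], config@fixation[2], config@fillValue,
               sep = "|")
  hit <- .gridCache[[key]]
  if (!is.null(hit)) return(hit)
  nR <- config@nRho; nT <- config@nTheta
  log2rho <- seq(config@log2RMin, config@log2RMax, length.out = nR)
  rho <- 2^log2rho
  theta <- (seq_len(nT) - 1) * 2 * pi / nT
  coords <- array(0, c(nR, nT, 2L))
  coords[, , 1] <- config@fixation[1] + rho %o% cos(theta)
  coords[, , 2] <- config@fixation[2] + rho %o% sin(theta)
  grid <- new("SamplingGrid", coords = coords, rho = rho, theta = theta,
              config = config)
  .gridCache[[key]] <- grid
  grid
}

#' Forward retinotopic transform (Cartesian to log-polar)
#'
#' Resamples a Cartesian image on the log-polar grid of `config` by bilinear
#' interpolation. Output rows index eccentricity (fovea at row 1), columns
#' index azimuth. Grid coordinates falling outside the source frame receive
#' `fillValue(config)`; with the default `log2RMax = 0` the grid lies inside
#' the unit disk and is therefore always in frame.
#'
#' @param image an `ImageRaster`, channels x H x W array, or matrix.
#' @param config a [FoveationConfig-class].
#' @return a [LogPolarImage-class].
#' @examples
#' cfg <- FoveationConfig(nTheta = 64, nRho = 64)
#' img <- ImageRaster(matrix(runif(32 * 32), 32, 32))
#' lp <- toLogPolar(img, cfg)
#' @export
toLogPolar <- function(image, config) {
  arr <- .rasterArray(image)
  if (any(!is.finite(arr))) stop("image contains non-finite pixels")
  LogPolarImage(.logPolarArray(arr, config), config)
}

## forward transform without S4 wrapping (hot path for classifiers)
.logPolarArray <- function(arr, config) {
  grid <- buildGrid(config)
  v <- .bilinearSample(arr, as.vector(grid@coords[, , 1]),
                       as.vector(grid@coords[, , 2]),
                       fill = config@fillValue)
  array(v, c(dim(arr)[1], config@nRho, config@nTheta))
}

#' Inverse retinotopic transform (log-polar to Cartesian)
#'
#' Reconstructs a Cartesian raster from a log-polar image. Each output pixel
#' is mapped to `(log2 r, theta)` relative to the fixation point and the
#' log-polar raster is sampled bilinearly, with circular interpolation along
#' the azimuth axis (columns near 2*pi blend with columns near 0). Pixels
#' beyond the outer radius receive the configured fill value; pixels inside
#' the innermost ring sample that ring, so the fovea center is not a hole.
#'
#' Reconstruction fidelity decreases with eccentricity: peripheral rings are
#' represented by fewer samples per unit area, so fine detail is lost there
#' first — the behaviour the foveated mapping is designed to have.
#'
#' @param lp a [LogPolarImage-class].
#' @param height,width output resolution (>= 2).
#' @return an [ImageRaster].
#' @export
fromLogPolar <- function(lp, height, width) {
  stopifnot(is(lp, "LogPolarImage"))
  if (height < 2 || width < 2) stop("output dimensions must be >= 2")
  cfg <- lp@config
  nR <- cfg@nRho; nT <- cfg@nTheta
  C <- dim(lp)[1]
  xy <- .gridXY(height, width)
  dx <- xy$x - cfg@fixation[1]
  dy <- xy$y - cfg@fixation[2]
  r <- sqrt(dx * dx + dy * dy)
  outside <- r > 2^cfg@log2RMax
  rc <- pmax(r, 2^cfg@log2RMin)           # inside the fovea: innermost ring
  # continuous row coordinate from log2 radius
  ic <- (log2(rc) - cfg@log2RMin) / (cfg@log2RMax - cfg@log2RMin) * (nR - 1) + 1
  ic <- pmin(pmax(ic, 1), nR)
  th <- atan2(dy, dx) %% (2 * pi)
  jc <- th / (2 * pi) * nT + 1            # in [1, nT + 1); wraps circularly

  i0 <- pmin(floor(ic), nR - 1); wy <- ic - i0
  j0 <- floor(jc); wx <- jc - j0
  j1 <- j0 %% nT + 1                      # circular neighbour
  j0 <- (j0 - 1) %% nT + 1

  flat <- lp@.Data
  dim(flat) <- c(C, nR * nT)
  v <- flat[, i0 + (j0 - 1) * nR, drop = FALSE]      * rep((1 - wx) * (1 - wy), each = C) +
       flat[, i0 + (j1 - 1) * nR, drop = FALSE]      * rep(wx * (1 - wy), each = C) +
       flat[, i0 + 1L + (j0 - 1) * nR, drop = FALSE] * rep((1 - wx) * wy, each = C) +
       flat[, i0 + 1L + (j1 - 1) * nR, drop = FALSE] * rep(wx * wy, each = C)
  if (any(outside)) v[, outside] <- cfg@fillValue
  ImageRaster(array(v, c(C, height, width)))
}

#' Circular crop mask
#'
#' Sets every pixel farther than `radius` from the fixation point to the fill
#' value, leaving the disk untouched. This is the Cartesian counterpart of
#' the circular field of view implied by the log-polar grid, used to make
#' Cartesian and retinotopic classifiers see the same image support.
#'
#' @param image an `ImageRaster`, array, or matrix.
#' @param radius normalized mask radius (> 0); `sqrt(2)` or more leaves any
#'   frame unchanged.
#' @param fixation normalized center of the disk.
#' @param fill value outside the disk.
#' @return an [ImageRaster].
#' @export
circularMask <- function(image, radius = 1, fixation = c(0, 0), fill = 0) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a single positive number")
  ImageRaster(.maskArray(.rasterArray(image), radius, fixation, fill))
}

.maskArray <- function(arr, radius = 1, fixation = c(0, 0), fill = 0) {
  d <- dim(arr)
  pc <- .pixelCenters(d[2], d[3])
  dist2 <- outer((pc$y - fixation[2])^2, (pc$x - fixation[1])^2, `+`)
  out <- dist2 > radius^2
  if (any(out)) {
    flat <- arr
    dim(flat) <- c(d[1], d[2] * d[3])
    flat[, as.vector(out)] <- fill
    dim(flat) <- d
    arr <- flat
  }
  arr
}
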