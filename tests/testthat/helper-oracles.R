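# Independent scalar oracles, deliberately written as naive double loops so
# they share no code path with the vectorized implementations they check.

# Bilinear sampling rule, one sample at a time: coordinates strictly outside
# [-1, 1]^2 give `fill`; in-frame coordinates clamp to border pixel centers;
# otherwise interpolate the four neighbouring pixel centers.
oracleBilinear <- function(mat, x, y, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  if (x < -1 || x > 1 || y < -1 || y > 1) return(fill)
  jc <- (x + 1) * W / 2 + 0.5
  ic <- (y + 1) * H / 2 + 0.5
  if (jc < 1) jc <- 1; if (jc > W) jc <- W
  if (ic < 1) ic <- 1; if (ic > H) ic <- H
  j0 <- floor(jc); if (j0 > W - 1) j0 <- W - 1
  i0 <- floor(ic); if (i0 > H - 1) i0 <- H - 1
  wx <- jc - j0; wy <- ic - i0
  mat[i0, j0] * (1 - wx) * (1 - wy) + mat[i0, j0 + 1] * wx * (1 - wy) +
    mat[i0 + 1, j0] * (1 - wx) * wy + mat[i0 + 1, j0 + 1] * wx * wy
}

# Forward log-polar transform, one output sample at a time.
oracleLogPolar <- function(mat, nTheta, nRho, log2RMin = -5, log2RMax = 0,
                           fixation = c(0, 0), fill = 0) {
  out <- matrix(0, nRho, nTheta)
  for (i in seq_len(nRho)) {
    rho <- 2^(log2RMin + (i - 1) * (log2RMax - log2RMin) / (nRho - 1))
    for (j in seq_len(nTheta)) {
      th <- (j - 1) * 2 * pi / nTheta
      out[i, j] <- oracleBilinear(mat,
                                  fixation[1] + rho * cos(th),
                                  fixation[2] + rho * sin(th), fill)
    }
  }
  out
}

# Best correlation achievable by any integer (row, column) shift of log-polar
# matrix `b` against `a`: columns wrap circularly (azimuth), rows shift with
# truncation (eccentricity), keeping at least `minOverlap` rows.
oracleBestShiftCor <- function(a, b, minOverlap = 8L) {
  n <- nrow(a); m <- ncol(a)
  best <- -1
  for (dc in 0:(m - 1)) {
    bc <- b[, ((seq_len(m) - 1 + dc) %% m) + 1, drop = FALSE]
    for (dr in (-(n - minOverlap)):(n - minOverlap)) {
      ra <- max(1, 1 + dr):min(n, n + dr)
      rb <- ra - dr
      va <- as.vector(a[ra, , drop = FALSE])
      vb <- as.vector(bc[rb, , drop = FALSE])
      if (sd(va) == 0 || sd(vb) == 0) next
      best <- max(best, cor(va, vb))
    }
  }
  best
}

# A deterministic classifier computed from simple image statistics, used for
# exact oracle-equality checks of the attack machinery.
statClassifier <- function(nClasses = 4L) {
  FunctionClassifier(function(imgs) {
    t(vapply(imgs, function(a) {
      v <- as.vector(a)
      z <- c(mean(v), sd(v), mean(v > 0.5), mean(abs(v - 0.5)))[seq_len(nClasses)]
      e <- exp(3 * z - max(3 * z))
      e / sum(e)
    }, numeric(nClasses)))
  }, nClasses = nClasses)
}

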