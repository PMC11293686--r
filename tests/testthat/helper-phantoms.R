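# Shared fixtures, built in code.

# Render a straight tube (bright band) through the image centre at a given
# angle, with an error-function edge so the half-maximum crossing sits at
# the true radius. Narrow tubes get a proportionally narrower edge so the
# profile still reaches the plateau intensity. Returns image + axis.
makeTube <- function(nr = 96, nc = 96, diameterPx = 8, angleDeg = 0,
                     intensity = 100, background = 5, edgeSigma = NULL,
                     noiseSd = 0, seed = 1) {
  if (is.null(edgeSigma)) edgeSigma <- min(2, diameterPx / 4)
  R <- diameterPx / 2
  th <- angleDeg * pi / 180
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  yy <- matrix(seq_len(nr), nr, nc) - cy
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  # signed distance to the line through centre with direction (sin, cos)
  d <- abs(-yy * cos(th) + xx * sin(th))
  img <- background + (intensity - background) * pnorm((R - d) / edgeSigma)
  if (noiseSd > 0) {
    set.seed(seed)
    img <- img + matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
  }
  half <- 0.45 * min(nr, nc)
  axis <- VesselAxis(rbind(c(cy - half * sin(th), cx - half * cos(th)),
                           c(cy + half * sin(th), cx + half * cos(th))))
  list(image = img, axis = axis, radius = R)
}

# Horizontal tube whose radius tapers linearly from r0 to r1 along x.
makeTaperTube <- function(nr = 64, nc = 120, d0 = 6, d1 = 10,
                          intensity = 100, background = 5,
                          edgeSigma = 2) {
  cy <- (nr + 1) / 2
  yy <- matrix(seq_len(nr), nr, nc) - cy
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Rx <- (d0 + (d1 - d0) * (xx - 1) / (nc - 1)) / 2
  img <- background +
    (intensity - background) * pnorm((Rx - abs(yy)) / edgeSigma)
  axis <- VesselAxis(rbind(c(cy, 8), c(cy, nc - 8)))
  list(image = img, axis = axis)
}

# Small flow phantom tuned for quick velocimetry tests.
quickFlow <- function(trueVelocity = 150, frameRate = 60, nFrames = 16,
                      noiseSd = 0, rbcCount = 3, seed = 1, ...) {
  flowPhantom(imageShape = c(48, 220), nFrames = nFrames,
              trueVelocity = trueVelocity, frameRate = frameRate,
              vesselAxis = rbind(c(24, 10), c(24, 210)),
              rbcCount = rbcCount, noiseSd = noiseSd, seed = seed, ...)
}

# Brute-force Otsu: exhaustive between-class-variance maximisation over
# all bin boundaries of a 256-bin histogram (independent of the
# cumulative-moments implementation).
bruteOtsu <- function(values, levels = 256L) {
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 0) return(NA_real_)
  breaks <- seq(lo, hi, length.out = levels + 1)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE),
                   1L), levels)
  cnt <- as.numeric(tabulate(bin, levels))
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  best <- -Inf; kbest <- NA_integer_
  for (k in seq_len(levels - 1)) {
    w0 <- sum(cnt[1:k]); w1 <- sum(cnt) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(cnt[1:k] * mids[1:k]) / w0
    m1 <- sum(cnt[(k + 1):levels] * mids[(k + 1):levels]) / w1
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best + 1e-9) { best <- sb; kbest <- k }
  }
  breaks[kbest + 1]
}

# Brute-force anisotropic EDT: per TRUE voxel, the minimum distance to
# any FALSE voxel centre.
bruteEdt <- function(mask, spacing) {
  d <- dim(mask)
  idx <- which(mask)
  bg <- which(!mask)
  out <- array(0, d)
  if (length(bg) == 0) { out[mask] <- Inf; return(out) }
  coord <- function(i) {
    i0 <- i - 1
    cbind(y = (i0 %% d[1]) * spacing[1],
          x = ((i0 %/% d[1]) %% d[2]) * spacing[2],
          z = (i0 %/% (d[1] * d[2])) * spacing[3])
  }
  ci <- coord(idx); cb <- coord(bg)
  for (k in seq_along(idx)) {
    dy <- cb[, 1] - ci[k, 1]; dx <- cb[, 2] - ci[k, 2]
    dz <- cb[, 3] - ci[k, 3]
    out[idx[k]] <- sqrt(min(dy * dy + dx * dx + dz * dz))
  }
  out
}

# Exact two-sided Mann-Whitney p by direct enumeration over assignment
# subsets (test-local oracle, written independently of the package).
enumMwP <- function(a, b) {
  nA <- length(a); n <- nA + length(b)
  r <- rank(c(a, b))
  uOf <- function(sel) sum(r[sel]) - nA * (nA + 1) / 2
  obs <- uOf(seq_len(nA))
  mu <- nA * (n - nA) / 2
  sets <- combn(n, nA)
  us <- apply(sets, 2, uOf)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Dense "capillary bed" cleared-organ phantom: a pancake-shaped organ
# filled with vertical capillaries (every z slice is crossed by many
# vessel lumina, like the cortical plexus) plus three horizontal vessels
# at the mid-plane that serve as diameter ROIs. Vessel diameter 8 um at
# 1/3 um raw voxel, so vessels stay well resolved after the 2x
# preprocessing downscale.
capillaryBedPhantom <- function(seed = 1, nVert = 254) {
  vox <- c(1 / 3, 1 / 3, 1)
  shape <- c(1152, 1152, 24)
  semi <- c(165, 165, 10)
  ctr <- shape * vox / 2
  set.seed(seed)
  specs <- list()
  horizY <- c(-70, 0, 70)
  r <- 4
  tries <- 0
  while (length(specs) < nVert && tries < 12000) {
    tries <- tries + 1
    y <- runif(1, -semi[1], semi[1]); x <- runif(1, -semi[2], semi[2])
    if (any(abs(y - horizY) < 14 & abs(x) < 115)) next
    rad2p <- ((abs(y) + r) / semi[1])^2 + ((abs(x) + r) / semi[2])^2
    if (rad2p >= 0.98) next
    zc <- semi[3] * sqrt(1 - rad2p)
    if (2 * zc < 6) next
    specs[[length(specs) + 1]] <- list(
      p0 = c(ctr[1] + y, ctr[2] + x, ctr[3] - zc),
      p1 = c(ctr[1] + y, ctr[2] + x, ctr[3] + zc), diameter = 2 * r)
  }
  nv <- length(specs)
  for (yoff in horizY)
    specs[[length(specs) + 1]] <- list(
      p0 = c(ctr[1] + yoff, ctr[2] - 110, ctr[3]),
      p1 = c(ctr[1] + yoff, ctr[2] + 110, ctr[3]), diameter = 8)
  ph <- clearedVolumePhantom(volumeShape = shape, voxelSize = vox,
    organSemiAxes = semi, vessels = specs, vesselIntensity = 200,
    organIntensity = 40, backgroundIntensity = 5, noiseSd = 3,
    seed = seed)
  list(ph = ph, horizontalAxes = ph$truth@vesselAxes[(nv + 1):(nv + 3)])
}
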