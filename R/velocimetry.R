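# Blood-flow velocimetry.
#
# Two estimators per vessel: (a) kymograph streak-slope analysis -- cells
# moving along the axis trace slanted streaks in the space-time image and
# the streak angle maximising the directional coherence of the rotated
# projection gives the speed; (b) automated centroid tracking of the dark
# (negative-contrast) red blood cells, the method performed by eye in the
# workflow this package models. The kymograph estimate is primary; tracking
# is the fallback when no coherent streak structure exists.

#' Extract a kymograph along a vessel axis
#'
#' Samples every frame at unit-spaced arc-length positions along the axis
#' (bilinear interpolation). Row t of the result is frame t; columns run
#' from the first axis vertex to the last.
#'
#' @param movie an aligned [FlowMovie-class].
#' @param axis a [VesselAxis-class].
#' @return A [Kymograph-class].
#' @export
extractKymograph <- function(movie, axis) {
  ax <- axisCoords(axis)
  L <- polyArcLength(ax)
  if (L < 4) stop("axis shorter than 4 px")
  s <- seq(0, floor(L))
  pts <- polylineAt(ax, s)$points
  fr <- frames(movie)
  n <- dim(fr)[3]
  k <- matrix(0, n, length(s))
  for (t in seq_len(n))
    k[t, ] <- bilinearSample(fr[, , t], pts[, 1], pts[, 2])
  new("Kymograph", data = k, pixelSize = pixelSize(movie),
      frameRate = frameRate(movie), axisId = axis@id)
}

# Directional coherence of the kymograph at streak angle phi (radians):
# weighted variance of the means of unit-width bins of the coordinate
# perpendicular to the streak direction (dt, dx) = (cos phi, sin phi).
streakCoherence <- function(z, tt, xx, phi, minCount = 3L) {
  w <- xx * cos(phi) - tt * sin(phi)
  bin <- as.integer(floor(w - min(w))) + 1L
  nb <- max(bin)
  bs <- binStats_cpp(z, bin, nb)
  cnt <- bs$count
  ok <- cnt >= minCount
  if (!any(ok)) return(0)
  m <- bs$sum[ok] / cnt[ok]
  sum(cnt[ok] * m^2) / sum(cnt[ok])
}

#' Estimate velocity from a kymograph
#'
#' Sweeps streak angles over (-90, 90) degrees at `angleRes` resolution,
#' takes the angle maximising directional coherence, refines it with a
#' fine local sweep plus parabolic interpolation, and converts the slope
#' (px/frame) to micrometres per second via pixel size and frame rate.
#' Positive velocities run from the first axis vertex towards the last.
#'
#' @param kymo a [Kymograph-class] with at least 8 rows.
#' @param angleRes coarse sweep resolution, degrees (default 0.25).
#' @param coherenceThreshold minimum ratio of best coherence to total
#'   variance; below it the kymograph is declared to have no measurable
#'   flow structure.
#' @return A [VelocityEstimate-class] with method "kymograph".
#' @export
estimateVelocityKymograph <- function(kymo, angleRes = 0.25,
                                      coherenceThreshold = 0.05) {
  k <- kymo@data
  if (nrow(k) < 8) stop("kymograph needs at least 8 rows")
  z <- as.vector(k - mean(k))
  v0 <- mean(z^2)
  if (v0 < .Machine$double.eps)
    stop("no measurable flow structure in kymograph")
  nt <- nrow(k); nx <- ncol(k)
  tt <- as.vector(row(k)) - 1
  xx <- as.vector(col(k)) - 1

  coh <- function(phiDeg)
    streakCoherence(z, tt, xx, phiDeg * pi / 180)
  coarse <- seq(-90 + angleRes, 90 - angleRes, by = angleRes)
  cs <- vapply(coarse, coh, numeric(1))
  best <- which.max(cs)
  if (cs[best] / v0 < coherenceThreshold)
    stop("no measurable flow structure in kymograph")
  fine <- seq(coarse[best] - 2 * angleRes, coarse[best] + 2 * angleRes,
              by = 0.01)
  fs <- vapply(fine, coh, numeric(1))
  b <- which.max(fs)
  phi <- fine[b]
  if (b > 1 && b < length(fs)) {
    den <- fs[b - 1] - 2 * fs[b] + fs[b + 1]
    if (abs(den) > .Machine$double.eps)
      phi <- phi + 0.005 * (fs[b - 1] - fs[b + 1]) / den
  }
  slope <- tan(phi * pi / 180)             # px per frame
  vel <- slope * kymo@pixelSize * kymo@frameRate

  # streak count at the best angle: runs of adjacent dark bins
  w <- xx * cos(phi * pi / 180) - tt * sin(phi * pi / 180)
  bin <- as.integer(floor(w - min(w))) + 1L
  nb <- max(bin)
  bs <- binStats_cpp(z, bin, nb)
  cnt <- bs$count
  m <- ifelse(cnt > 0, bs$sum / pmax(cnt, 1), 0)
  dark <- m < -0.25 * max(abs(m))
  nStreaks <- sum(diff(c(FALSE, dark)) == 1)
  new("VelocityEstimate", velocity = vel, method = "kymograph",
      nObservations = max(1L, nStreaks), dispersion = 0,
      roi = kymo@axisId)
}

#' Detect negative-contrast RBC centroids in one frame
#'
#' Inverts intensities inside the lumen mask (dark cells become bright),
#' thresholds at `sensitivity` times the maximum depth below the lumen
#' level (median intensity inside the mask), labels 8-connected blobs, and
#' returns their depth-weighted centroids. An empty matrix is a valid
#' result.
#'
#' @param frame numeric matrix `[y, x]`.
#' @param lumenMask logical matrix, in-lumen pixels.
#' @param sensitivity fraction of the maximum depth used as threshold.
#' @param minArea minimum blob size, px.
#' @param minContrast minimum (max depth)/(lumen level) to call any
#'   detection; guards against noise-only frames.
#' @param erodePx erode the lumen mask by this many px before detecting,
#'   so the dimmer lumen-edge band is not mistaken for cells (0 disables).
#' @return `k x 2` matrix of (y, x) centroids (possibly 0 rows).
#' @export
detectRbcCentroids <- function(frame, lumenMask, sensitivity = 0.5,
                               minArea = 4L, minContrast = 0.2,
                               erodePx = 2) {
  if (!any(lumenMask)) stop("lumen mask is empty")
  if (erodePx > 0) {
    er <- distanceTransform(lumenMask)[, , 1] >= erodePx
    if (any(er)) lumenMask <- er
  }
  lumenLevel <- stats::median(frame[lumenMask])
  depth <- lumenLevel - frame
  depth[!lumenMask] <- 0
  depth[depth < 0] <- 0
  mx <- max(depth)
  if (mx <= 0 || mx / max(abs(lumenLevel), .Machine$double.eps) < minContrast)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x"))))
  lab <- label8(depth > sensitivity * mx)
  nlab <- max(lab)
  if (nlab == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x"))))
  ys <- row(lab); xs <- col(lab)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nlab)) {
    sel <- lab == i
    if (sum(sel) < minArea) next
    wgt <- depth[sel]
    out <- rbind(out, c(sum(ys[sel] * wgt) / sum(wgt),
                        sum(xs[sel] * wgt) / sum(wgt)))
  }
  colnames(out) <- c("y", "x")
  out
}

#' Track RBCs and estimate velocity
#'
#' Detects centroids in every frame, links them between consecutive frames
#' by greedy mutual nearest-neighbour matching within a gating radius
#' derived from `vMax`, projects each displacement onto the axis (signed
#' arc-length difference), and reports the mean link velocity per vessel.
#' Links whose arc position falls within `endGuard` px of either axis end
#' are discarded (cells entering or leaving the field).
#'
#' @param movie an aligned [FlowMovie-class] with >= 2 frames.
#' @param axis a [VesselAxis-class].
#' @param lumenMask logical matrix of in-lumen pixels.
#' @param vMax largest plausible speed, micrometres per second; sets the
#'   gating radius (1.5 x the implied per-frame displacement) and the
#'   default end guard (1 x).
#' @param endGuard guard width at the axis ends, px; default derived from
#'   `vMax`.
#' @param ... passed to [detectRbcCentroids()].
#' @return A [VelocityEstimate-class] with method "tracking".
#' @export
trackRbcVelocity <- function(movie, axis, lumenMask, vMax = 1000,
                             endGuard = NULL, ...) {
  fr <- frames(movie)
  n <- dim(fr)[3]
  if (n < 2) stop("movie must have at least 2 frames")
  ps <- pixelSize(movie); fps <- frameRate(movie)
  dispMax <- vMax / (fps * ps)
  gate <- 1.5 * dispMax
  if (is.null(endGuard)) endGuard <- dispMax
  ax <- axisCoords(axis)
  L <- polyArcLength(ax)

  cents <- lapply(seq_len(n), function(t)
    detectRbcCentroids(fr[, , t], lumenMask, ...))
  arcs <- lapply(cents, function(cm) {
    if (nrow(cm) == 0) return(numeric(0))
    distanceToPolyline(cm, ax)$arc
  })

  linkV <- numeric(0)
  for (t in seq_len(n - 1)) {
    a <- cents[[t]]; b <- cents[[t + 1]]
    if (nrow(a) == 0 || nrow(b) == 0) next
    dmat <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    dmat <- sqrt(dmat)
    ord <- order(dmat)
    usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
    for (o in ord) {
      if (dmat[o] > gate) break
      i <- (o - 1) %% nrow(a) + 1
      j <- (o - 1) %/% nrow(a) + 1
      if (usedA[i] || usedB[j]) next
      usedA[i] <- TRUE; usedB[j] <- TRUE
      s1 <- arcs[[t]][i]; s2 <- arcs[[t + 1]][j]
      if (min(s1, s2) < endGuard || max(s1, s2) > L - endGuard) next
      linkV <- c(linkV, (s2 - s1) * ps * fps)
    }
  }
  if (length(linkV) == 0) stop("no trackable cells")
  new("VelocityEstimate", velocity = mean(linkV), method = "tracking",
      nObservations = length(linkV),
      dispersion = if (length(linkV) > 1) stats::sd(linkV) else 0,
      roi = axis@id)
}

#' Per-vessel velocity with automatic-first policy
#'
#' Runs the kymograph estimator and falls back to centroid tracking when
#' no coherent streak structure is found, mirroring the convention of
#' measuring manually only when the automatic method fails.
#'
#' @inheritParams trackRbcVelocity
#' @param ... passed to the tracking fallback.
#' @return A [VelocityEstimate-class].
#' @export
estimateVesselVelocity <- function(movie, axis, lumenMask, vMax = 1000,
                                   ...) {
  tryCatch(
    estimateVelocityKymograph(extractKymograph(movie, axis)),
    error = function(e)
      trackRbcVelocity(movie, axis, lumenMask, vMax = vMax, ...))
}
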