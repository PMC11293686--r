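# Cleared-organ 3D morphometry.
#
# Chain: preprocess the volume, segment the organ, threshold an
# anisotropy-aware Euclidean distance map to a peripheral shell, draw
# random non-overlapping square fields of view (FOV) whose centroids lie
# in the shell, and score each FOV for vessel diameter, count, frequency
# (segments per mm^2 of organ) and Otsu vessel-area fraction.

#' Anisotropic 3D Euclidean distance transform
#'
#' For every TRUE voxel, the exact Euclidean distance (in physical units)
#' to the centre of the nearest FALSE voxel, honouring anisotropic voxel
#' spacing; FALSE voxels map to 0 and the array border is not treated as
#' background. Computed by the separable lower-envelope algorithm in
#' compiled code.
#'
#' @param mask logical array `[y, x, z]` (a matrix is treated as one
#'   slice).
#' @param spacing numeric length 3, micrometres per voxel along (y, x, z).
#' @return Numeric array of distances, same shape as `mask`; `Inf` where
#'   no background voxel exists.
#' @export
distanceTransform <- function(mask, spacing = c(1, 1, 1)) {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1))
  stopifnot(length(dim(mask)) == 3)
  out <- edt3d_cpp(as.logical(mask), as.integer(dim(mask)),
                   as.numeric(spacing))
  array(out, dim(mask))
}

#' Otsu threshold of an intensity sample
#'
#' Histogram threshold maximising the between-class variance, on a
#' 256-bin histogram spanning the sample's own intensity range. Ties go
#' to the lowest threshold. Foreground is `value > threshold`.
#'
#' @param values numeric vector (e.g. the pixels of one FOV).
#' @param levels number of histogram bins (default 256).
#' @return Threshold on the intensity scale, or `NA` if the sample is
#'   constant.
#' @export
otsuThreshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 0) return(NA_real_)
  breaks <- seq(lo, hi, length.out = levels + 1)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE),
                   1L), levels)
  cnt <- as.numeric(tabulate(bin, levels))
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w <- cumsum(cnt)
  m <- cumsum(cnt * mids)
  tot <- w[levels]; mtot <- m[levels]
  k <- seq_len(levels - 1)
  w0 <- w[k]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, levels - 1)
  sb[valid] <- (mtot * w0[valid] - m[k][valid] * tot)^2 /
    (w0[valid] * w1[valid])
  kbest <- which.max(sb)        # first maximum: lowest threshold on ties
  breaks[kbest + 1]
}

#' Segment the organ outline in a cleared volume
#'
#' Threshold mode: Otsu on a heavily smoothed copy (2D Gaussian per
#' slice), keep the largest 3D connected component, fill holes per slice.
#' Manual mode: rasterise user-supplied per-slice outline polygons. The
#' learning-based masking some workflows use is deliberately out of
#' scope; manual tracing is an accepted equal alternative.
#'
#' @param volume a (preprocessed) [VolumeStack-class].
#' @param method "threshold" or "manual".
#' @param polygons manual mode: list, one element per z slice, each a
#'   `n x 2` (y, x) px polygon (or NULL for empty slices).
#' @param smoothSigma Gaussian SD (px) for the smoothed copy, threshold
#'   mode (capped so the kernel fits the slice).
#' @param clipQuantile intensities above this quantile are clipped before
#'   smoothing, so bright sparse vessels do not drag the organ/background
#'   threshold upward and erode the organ rim.
#' @return An [OrganMask-class].
#' @export
segmentOrganMask <- function(volume, method = c("threshold", "manual"),
                             polygons = NULL, smoothSigma = 6,
                             clipQuantile = 0.95) {
  method <- match.arg(method)
  v <- voxels(volume)
  d <- dim(v)
  if (method == "manual") {
    if (is.null(polygons)) stop("manual method needs polygons")
    mask <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      if (k <= length(polygons) && !is.null(polygons[[k]]) &&
          nrow(polygons[[k]]) >= 3)
        mask[, , k] <- rasterizePolygon(polygons[[k]], d[1], d[2])
    }
    if (!any(mask)) stop("organ mask is empty")
    return(new("OrganMask", mask = mask, voxelSize = voxelSize(volume),
               provenance = "manual"))
  }
  if (max(v) - min(v) <= 0) stop("organ mask is empty (constant volume)")
  cap <- stats::quantile(v, clipQuantile)
  v <- pmin(v, cap)
  sig <- min(smoothSigma, (min(d[1:2]) - 2) / 6.5)
  sm <- array(0, d)
  for (k in seq_len(d[3])) sm[, , k] <- gblur2d(v[, , k], sig)
  thr <- otsuThreshold(as.vector(sm))
  if (is.na(thr)) stop("organ mask is empty (constant volume)")
  mask <- sm > thr
  if (!any(mask)) stop("organ mask is empty")
  lab <- label3d(mask)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (any(sl))
      mask[, , k] <- EBImage::imageData(EBImage::fillHull(sl * 1)) > 0
  }
  new("OrganMask", mask = mask, voxelSize = voxelSize(volume),
      provenance = "threshold")
}

#' Peripheral shell of an organ mask
#'
#' Thresholds the organ's Euclidean distance map to the voxels strictly
#' closer than `depth` micrometres to the organ edge. The "downscaled"
#' fidelity mode reproduces a workflow that halves the mask in y/x before
#' the distance map and upscales the result by 2 (coarser but cheaper);
#' "full" computes the distance map at full resolution.
#'
#' @param organ an [OrganMask-class].
#' @param depth shell depth, micrometres (default 150).
#' @param fidelity "full" or "downscaled".
#' @return A [ShellMask-class].
#' @export
distanceShell <- function(organ, depth = 150,
                          fidelity = c("full", "downscaled")) {
  fidelity <- match.arg(fidelity)
  stopifnot(depth > 0)
  vs <- voxelSize(organ)
  m <- maskArray(organ)
  if (fidelity == "full") {
    dist <- distanceTransform(m, spacing = vs[c("y", "x", "z")])
    shell <- m & dist < depth
  } else {
    d <- dim(m)
    ny2 <- d[1] %/% 2; nx2 <- d[2] %/% 2
    small <- array(FALSE, c(ny2, nx2, d[3]))
    for (k in seq_len(d[3]))
      small[, , k] <- blockDownscale2(m[, , k] * 1) >= 0.5
    dist2 <- distanceTransform(small,
                               spacing = c(vs["y"] * 2, vs["x"] * 2,
                                           vs["z"]))
    up <- array(FALSE, d)
    distUp <- array(Inf, d)
    iy <- pmin(pmax(ceiling(seq_len(d[1]) / 2), 1), ny2)
    ix <- pmin(pmax(ceiling(seq_len(d[2]) / 2), 1), nx2)
    for (k in seq_len(d[3])) distUp[, , k] <- dist2[iy, ix, k]
    shell <- m & distUp < depth
  }
  new("ShellMask", mask = shell, voxelSize = vs, depth = depth)
}

#' Sample random non-overlapping square FOVs in the shell
#'
#' Rejection-samples candidate centroids uniformly from shell voxels
#' (seeded), accepting a candidate when its square footprint lies inside
#' the volume and does not overlap (in y/x) any accepted FOV. Stops at
#' `n` accepted or errors after `maxTries` candidates, reporting how many
#' were placed.
#'
#' @param shell a [ShellMask-class].
#' @param n number of FOVs (default 20).
#' @param side FOV side, micrometres (default 300).
#' @param seed integer seed; identical seeds give identical FOV sets.
#' @param maxTries candidate budget (default 10000).
#' @return data.frame with one row per FOV: pixel rectangle (`y0`, `x0`,
#'   `sideY`, `sideX`), z slice, and centroid in micrometres.
#' @export
sampleFovs <- function(shell, n = 20L, side = 300, seed = 1L,
                       maxTries = 10000L) {
  stopifnot(n >= 1, side > 0)
  m <- maskArray(shell)
  if (!any(m)) stop("shell mask is empty")
  vs <- voxelSize(shell)
  d <- dim(m)
  sideY <- max(1L, round(side / vs["y"]))
  sideX <- max(1L, round(side / vs["x"]))
  idx <- which(m)
  acc <- list()
  withSeed(seed, {
    tries <- 0L
    while (length(acc) < n && tries < maxTries) {
      tries <- tries + 1L
      v <- idx[sample.int(length(idx), 1L)]
      v0 <- v - 1L
      iy <- v0 %% d[1] + 1L
      ix <- (v0 %/% d[1]) %% d[2] + 1L
      iz <- v0 %/% (d[1] * d[2]) + 1L
      y0 <- iy - sideY %/% 2L
      x0 <- ix - sideX %/% 2L
      if (y0 < 1 || x0 < 1 || y0 + sideY - 1 > d[1] ||
          x0 + sideX - 1 > d[2]) next
      rect <- c(y0, x0, sideY, sideX)
      clash <- any(vapply(acc, function(a)
        rectsOverlap(rect, c(a$y0, a$x0, a$sideY, a$sideX)), logical(1)))
      if (clash) next
      acc[[length(acc) + 1L]] <- list(
        y0 = y0, x0 = x0, sideY = sideY, sideX = sideX, zSlice = iz,
        centroidY = (iy - 0.5) * unname(vs["y"]),
        centroidX = (ix - 0.5) * unname(vs["x"]),
        centroidZ = (iz - 0.5) * unname(vs["z"]))
    }
  })
  if (length(acc) < n)
    stop(sprintf("placed only %d of %d FOVs within %d candidates",
                 length(acc), n, maxTries))
  out <- do.call(rbind, lapply(seq_along(acc), function(i)
    data.frame(fov = i, acc[[i]])))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "sideUm") <- side
  out
}

#' Otsu vessel-area fraction of one FOV
#'
#' Otsu threshold on the FOV's own 256-bin histogram; the vessel-area
#' percent is 100 x vessel pixels / total FOV pixels. When an organ mask
#' slice is given, the histogram is restricted to organ pixels (so a FOV
#' straddling the organ boundary thresholds parenchyma against vessels,
#' not organ against background) and vessel pixels outside the organ are
#' discarded. A constant FOV yields 0% with a warning. FOVs whose Otsu
#' separation is weak -- effectiveness (between-class over total
#' variance) below `minSeparation` -- contain no vessel/background
#' structure, only noise, and report 0%.
#'
#' @param fovImage numeric matrix, the FOV pixels.
#' @param organMaskSlice optional logical matrix, organ pixels in the FOV.
#' @param minSeparation minimum Otsu effectiveness to accept the
#'   threshold (default 0.8; pure noise scores about 0.64).
#' @return list(percent, threshold, separation, mask).
#' @export
fovVesselArea <- function(fovImage, organMaskSlice = NULL,
                          minSeparation = 0.8) {
  none <- function(sep = NA_real_, thr = NA_real_)
    list(percent = 0, threshold = thr, separation = sep,
         mask = matrix(FALSE, nrow(fovImage), ncol(fovImage)))
  vals <- if (is.null(organMaskSlice)) as.vector(fovImage)
          else fovImage[organMaskSlice]
  if (length(vals) < 2) return(none())
  thr <- otsuThreshold(vals)
  if (is.na(thr)) {
    warning("constant FOV: no separable threshold, reporting 0%")
    return(none())
  }
  lo <- vals <= thr
  if (!any(lo) || all(lo)) return(none(0, thr))
  w0 <- mean(lo)
  sb <- w0 * (1 - w0) * (mean(vals[!lo]) - mean(vals[lo]))^2
  tot <- mean((vals - mean(vals))^2)
  sep <- if (tot > 0) sb / tot else 0
  if (sep < minSeparation) return(none(sep, thr))
  mask <- fovImage > thr
  if (!is.null(organMaskSlice)) mask <- mask & organMaskSlice
  list(percent = 100 * sum(mask) / length(fovImage), threshold = thr,
       separation = sep, mask = mask)
}

#' Count vessel segments in a FOV mask
#'
#' 8-connected components of the binary vessel mask, keeping components
#' at least as large as a 2 um diameter disk at the working pixel size
#' (a minimum-size filter against speckle).
#'
#' @param mask logical matrix from [fovVesselArea()].
#' @param pixelSize micrometres per pixel (used for the default filter).
#' @param minArea override the minimum component area, px.
#' @return Integer count.
#' @export
countVesselsInFov <- function(mask, pixelSize = 1, minArea = NULL) {
  if (is.null(minArea)) minArea <- max(1, round(pi * (1 / pixelSize)^2))
  if (!any(mask)) return(0L)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= minArea)
}

#' Vessel frequency
#'
#' Vessel segments per mm^2 of organ area within the FOV.
#'
#' @param vesselCount integer count from [countVesselsInFov()].
#' @param organAreaMm2 organ area inside the FOV, mm^2 (> 0).
#' @return Frequency in segments/mm^2.
#' @export
fovVesselFrequency <- function(vesselCount, organAreaMm2) {
  if (organAreaMm2 <= 0) stop("organ area must be positive")
  vesselCount / organAreaMm2
}

# Liang-Barsky clip of a segment to rows y0..y1, cols x0..x1 (inclusive).
clipSegmentToRect <- function(p0, p1, y0, y1, x0, x1) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (s in list(c(-d[1], p0[1] - y0), c(d[1], y1 - p0[1]),
                 c(-d[2], p0[2] - x0), c(d[2], x1 - p0[2]))) {
    p <- s[1]; q <- s[2]
    if (p == 0) {
      if (q < 0) return(NULL)
    } else {
      r <- q / p
      if (p < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
      else { if (r < t0) return(NULL); if (r < t1) t1 <- r }
    }
  }
  rbind(p0 + t0 * d, p0 + t1 * d)
}

#' Run the full cleared-organ morphometry chain
#'
#' preprocess -> organ mask -> distance shell -> FOV sampling -> per-FOV
#' vessel area %, count, frequency and (when centreline ROIs are
#' supplied) cross-line FWHM diameter. Diameters are measured per vessel
#' on the z slice through that vessel's own centreline, on the portion of
#' the centreline crossing the FOV footprint; counts and areas use the
#' slice at the FOV centroid.
#'
#' @param volume raw [VolumeStack-class].
#' @param vesselAxes optional list of [VesselAxis-class] in pixel
#'   coordinates of the raw volume, each with a `zSlice` attribute (raw
#'   voxel units), e.g. the `vesselAxes` of a phantom truth object.
#' @param preprocess apply [preprocessVolume()] first (default TRUE).
#' @param maskMethod,polygons passed to [segmentOrganMask()].
#' @param shellDepth shell depth, micrometres (default 150).
#' @param nFov,fovSide number and side (um) of sampled FOVs.
#' @param seed integer seed for FOV sampling.
#' @param minVesselArea minimum component area in px for counting
#'   (default: 2 um disk at the working pixel size).
#' @param crossLineSpacing spacing of diameter cross-lines, px.
#' @param crossHalfLength half-length of diameter cross-lines, px; keep
#'   it below the typical vessel separation so a cross-line does not
#'   reach into a neighbouring vessel (default 12 px).
#' @param maxTries FOV candidate budget.
#' @return list(fovTable, summary, organMask, shellMask, volume) where
#'   `summary` holds per-organ means and `volume` is the preprocessed
#'   stack the measurements were made on.
#' @export
runMorphometry <- function(volume, vesselAxes = NULL, preprocess = TRUE,
                           maskMethod = "threshold", polygons = NULL,
                           shellDepth = 150, nFov = 20L, fovSide = 300,
                           seed = 1L, minVesselArea = NULL,
                           crossLineSpacing = 2, crossHalfLength = 12,
                           maxTries = 10000L) {
  scale <- if (preprocess) 2 else 1
  vol <- if (preprocess) preprocessVolume(volume) else volume
  organ <- segmentOrganMask(vol, method = maskMethod, polygons = polygons)
  shell <- distanceShell(organ, depth = shellDepth)
  stopifnot(all(maskArray(shell) <= maskArray(organ)))
  fovs <- sampleFovs(shell, n = nFov, side = fovSide, seed = seed,
                     maxTries = maxTries)
  vs <- voxelSize(vol)
  pxUm <- unname(vs["y"])
  v <- voxels(vol)
  om <- maskArray(organ)

  axesScaled <- NULL
  if (!is.null(vesselAxes)) {
    axesScaled <- lapply(vesselAxes, function(a) {
      co <- (axisCoords(a) - 0.5) / scale + 0.5
      zs <- attr(a, "zSlice")
      out <- VesselAxis(co, id = a@id)
      attr(out, "zSlice") <- if (is.null(zs)) NULL else zs  # z not halved
      out
    })
  }

  res <- lapply(seq_len(nrow(fovs)), function(i) {
    f <- fovs[i, ]
    ys <- f$y0:(f$y0 + f$sideY - 1)
    xs <- f$x0:(f$x0 + f$sideX - 1)
    img <- v[ys, xs, f$zSlice]
    omSlice <- om[ys, xs, f$zSlice]
    area <- fovVesselArea(img, organMaskSlice = omSlice)
    cnt <- countVesselsInFov(area$mask, pixelSize = pxUm,
                             minArea = minVesselArea)
    organAreaMm2 <- sum(omSlice) * unname(vs["y"]) * unname(vs["x"]) / 1e6
    freq <- if (organAreaMm2 > 0) fovVesselFrequency(cnt, organAreaMm2)
            else NA_real_
    dia <- NA_real_
    if (!is.null(axesScaled)) {
      ds <- numeric(0)
      for (a in axesScaled) {
        co <- axisCoords(a)
        clip <- clipSegmentToRect(co[1, ], co[nrow(co), ],
                                  f$y0, f$y0 + f$sideY - 1,
                                  f$x0, f$x0 + f$sideX - 1)
        if (is.null(clip)) next
        if (sqrt(sum((clip[2, ] - clip[1, ])^2)) < 3 * crossLineSpacing)
          next
        zax <- attr(a, "zSlice")
        z <- if (is.null(zax)) f$zSlice
             else min(max(round(zax), 1L), dim(v)[3])
        sliceImg <- v[, , z]
        est <- tryCatch(
          suppressWarnings(
          measureVesselDiameter(sliceImg, VesselAxis(clip, id = a@id),
                                spacing = crossLineSpacing,
                                halfLength = min(crossHalfLength,
                                                 min(dim(sliceImg)) %/%
                                                   2 - 1),
                                pixelSize = pxUm)),
          error = function(e) NULL)
        if (!is.null(est)) ds <- c(ds, diameter(est))
      }
      if (length(ds)) dia <- mean(ds)
    }
    data.frame(fov = f$fov, zSlice = f$zSlice, y0 = f$y0, x0 = f$x0,
               sideY = f$sideY, sideX = f$sideX,
               centroidY = f$centroidY, centroidX = f$centroidX,
               centroidZ = f$centroidZ,
               organAreaMm2 = organAreaMm2, vesselCount = cnt,
               vesselAreaPercent = area$percent,
               vesselFrequency = freq, meanDiameterUm = dia)
  })
  tab <- do.call(rbind, res)
  summary <- list(
    nFov = nrow(tab),
    meanDiameterUm = mean(tab$meanDiameterUm, na.rm = TRUE),
    meanAreaPercent = mean(tab$vesselAreaPercent, na.rm = TRUE),
    meanFrequency = mean(tab$vesselFrequency, na.rm = TRUE),
    meanVesselCount = mean(tab$vesselCount),
    seed = as.integer(seed))
  list(fovTable = tab, summary = summary, organMask = organ,
       shellMask = shell, volume = vol)
}
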