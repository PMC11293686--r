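# Ground-truthed synthetic phantoms.
#
# The flow phantom emulates an intravital two-photon movie of an Evans-blue
# labelled vessel: a bright lumen on a dark background, dark
# (negative-contrast) red blood cells advected along the centreline at a
# known speed, optional plasma leak raising the extravascular level, rigid
# per-frame jitter, and Gaussian read noise. The cleared-volume phantom
# emulates a whole cleared organ: an ellipsoidal parenchyma containing
# cylindrical vessels of known diameter. Every fixed quantity is returned
# as a PhantomTruth object.

#' Generate a ground-truthed flow movie phantom
#'
#' Renders a time-lapse movie of a single vessel with dark RBCs moving at a
#' known velocity. The lumen is a tube of the given diameter around
#' `vesselAxis` with an error-function edge (`edgeSigma` px of smoothing),
#' so the half-maximum crossing of a perpendicular intensity profile sits
#' exactly at the true radius. RBCs are Gaussian-profile dark disks
#' (diameter = full width at half depth) advected along the axis at
#' `trueVelocity`, with even spacing plus a small seeded offset
#' (single-file capillary flow); cells wrap around the axis ends.
#' Extravascular pixels take
#' `backgroundIntensity + leakFraction * lumenIntensity`.
#'
#' @param imageShape c(height, width) in pixels.
#' @param pixelSize micrometres per pixel (default 0.31).
#' @param frameRate frames per second (30, 60 or 120 in the modelled
#'   acquisitions).
#' @param nFrames number of frames.
#' @param vesselAxis [VesselAxis-class] or `n x 2` (y, x) matrix; default a
#'   horizontal centreline spanning the frame with a 10 px margin.
#' @param vesselDiameter true diameter, micrometres.
#' @param lumenIntensity,backgroundIntensity,rbcIntensity arbitrary units;
#'   `rbcIntensity` must be below `lumenIntensity` (negative contrast).
#' @param rbcCount number of circulating cells.
#' @param rbcDiameter cell diameter (full width at half depth), micrometres.
#' @param trueVelocity signed micrometres per second along the axis.
#' @param leakFraction extravascular leak fraction (>= 0).
#' @param jitterAmplitude per-frame rigid shift amplitude, px; shifts are
#'   i.i.d. uniform on [-amplitude, amplitude] in y and x and recorded in
#'   the truth object.
#' @param noiseSd Gaussian noise SD, arbitrary units.
#' @param edgeSigma lumen edge smoothing, px.
#' @param seed integer seed; identical parameters and seed give identical
#'   output.
#' @return list(movie = [FlowMovie-class], truth = [PhantomTruth-class]).
#' @export
flowPhantom <- function(imageShape = c(64, 256), pixelSize = 0.31,
                        frameRate = 60, nFrames = 32, vesselAxis = NULL,
                        vesselDiameter = 8, lumenIntensity = 150,
                        backgroundIntensity = 10, rbcCount = 4,
                        rbcDiameter = 5, rbcIntensity = 30,
                        trueVelocity = 150, leakFraction = 0,
                        jitterAmplitude = 0, noiseSd = 5, edgeSigma = 2,
                        seed = 1L) {
  stopifnot(pixelSize > 0, frameRate > 0, nFrames >= 1,
            vesselDiameter > 0, leakFraction >= 0, noiseSd >= 0)
  if (rbcIntensity < 0 || rbcIntensity >= lumenIntensity)
    stop("rbcIntensity must satisfy 0 <= rbcIntensity < lumenIntensity")
  if (rbcCount > 0 && rbcDiameter > vesselDiameter)
    stop("rbcDiameter must not exceed vesselDiameter")
  nr <- imageShape[1]; nc <- imageShape[2]
  if (is.null(vesselAxis))
    vesselAxis <- VesselAxis(rbind(c(nr / 2, 10), c(nr / 2, nc - 10)))
  if (is.matrix(vesselAxis)) vesselAxis <- VesselAxis(vesselAxis)
  ax <- axisCoords(vesselAxis)
  if (any(ax[, 1] < 1) || any(ax[, 1] > nr) ||
      any(ax[, 2] < 1) || any(ax[, 2] > nc))
    stop("vessel axis exits image bounds")

  R <- vesselDiameter / (2 * pixelSize)           # lumen radius, px
  rbcSigma <- (rbcDiameter / pixelSize) / (2 * sqrt(2 * log(2)))
  vPx <- trueVelocity / (frameRate * pixelSize)   # px per frame
  L <- polyArcLength(ax)
  extra <- backgroundIntensity + leakFraction * lumenIntensity
  depth <- lumenIntensity - rbcIntensity

  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc)

  out <- withSeed(seed, {
    shifts <- if (jitterAmplitude > 0)
      matrix(runif(2 * nFrames, -jitterAmplitude, jitterAmplitude),
             nFrames, 2)
    else matrix(0, nFrames, 2)
    s0 <- if (rbcCount > 0)
      (seq_len(rbcCount) - 1) * L / rbcCount +
        runif(rbcCount, 0, 0.2 * L / max(1, rbcCount))
    else numeric(0)
    noise <- if (noiseSd > 0) rnorm(nr * nc * nFrames, 0, noiseSd) else NULL
    list(shifts = shifts, s0 = s0, noise = noise)
  })
  shifts <- out$shifts; s0 <- out$s0

  tubeField <- function(dy, dx) {
    pts <- cbind(as.vector(yy) - dy, as.vector(xx) - dx)
    d <- distanceToPolyline(pts, ax)$distance
    edge <- pnorm((R - d) / edgeSigma)
    matrix(extra + (lumenIntensity - extra) * edge, nr, nc)
  }
  base0 <- tubeField(0, 0)

  mov <- array(0, dim = c(nr, nc, nFrames))
  for (t in seq_len(nFrames)) {
    dy <- shifts[t, 1]; dx <- shifts[t, 2]
    fr <- if (dy == 0 && dx == 0) base0 else tubeField(dy, dx)
    if (rbcCount > 0) {
      s <- (s0 + vPx * (t - 1)) %% L
      ctr <- polylineAt(ax, s)$points
      for (i in seq_len(rbcCount)) {
        cy <- ctr[i, 1] + dy; cx <- ctr[i, 2] + dx
        w <- ceiling(4 * rbcSigma)
        ys <- max(1, floor(cy - w)):min(nr, ceiling(cy + w))
        xs <- max(1, floor(cx - w)):min(nc, ceiling(cx + w))
        if (!length(ys) || !length(xs)) next
        r2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
        fr[ys, xs] <- fr[ys, xs] - depth * exp(-r2 / (2 * rbcSigma^2))
      }
    }
    mov[, , t] <- fr
  }
  if (!is.null(out$noise)) mov <- mov + array(out$noise, dim = dim(mov))

  lum <- distanceToPolyline(cbind(as.vector(yy), as.vector(xx)),
                            ax)$distance <= R
  truth <- new("PhantomTruth",
               trueVelocity = trueVelocity,
               trueDiameters = c(v1 = vesselDiameter),
               trueLeakFraction = leakFraction,
               injectedShifts = shifts,
               lumenMask = matrix(lum, nr, nc),
               organMask = NULL, vesselMask = NULL,
               trueVesselVolumeFraction = numeric(0),
               vesselAxes = list(v1 = vesselAxis),
               seed = as.integer(seed))
  list(movie = FlowMovie(mov, pixelSize = pixelSize, frameRate = frameRate),
       truth = truth)
}

#' Generate a ground-truthed cleared-organ volume phantom
#'
#' Builds a 3D volume containing an ellipsoidal organ (at `organIntensity`)
#' on a darker background, with hard-edged cylindrical vessels at
#' `vesselIntensity` placed inside the organ. Vessels run parallel to the
#' xy-plane (constant z), so a z-slice through a vessel centreline shows a
#' band of width equal to the true diameter; their chords span an organ
#' ellipsoid conservatively shrunk by the vessel radius so the whole
#' cylinder stays inside. Either supply explicit `vessels` specs or let
#' `nVessels` be placed at seeded random positions/orientations.
#'
#' @param volumeShape c(ny, nx, nz) voxels.
#' @param voxelSize micrometres per voxel along (y, x, z).
#' @param organSemiAxes ellipsoid semi-axes (y, x, z), micrometres; the
#'   organ is centred in the volume.
#' @param nVessels number of randomly placed vessels.
#' @param vesselDiameters micrometres, recycled over vessels.
#' @param vessels optional list of explicit specs, each
#'   `list(p0 = c(y, x, z), p1 = c(y, x, z), diameter = )` in micrometres
#'   from the volume corner; overrides random placement.
#' @param vesselIntensity,organIntensity,backgroundIntensity arbitrary
#'   units.
#' @param noiseSd Gaussian noise SD.
#' @param minChord minimum acceptable vessel length, micrometres.
#' @param maxTries placement retry budget.
#' @param seed integer seed.
#' @return list(volume = [VolumeStack-class], truth = [PhantomTruth-class]).
#' @export
clearedVolumePhantom <- function(volumeShape = c(128, 128, 48),
                                 voxelSize = c(y = 1, x = 1, z = 2),
                                 organSemiAxes = c(55, 55, 40),
                                 nVessels = 12, vesselDiameters = 8,
                                 vessels = NULL, vesselIntensity = 200,
                                 organIntensity = 40,
                                 backgroundIntensity = 5, noiseSd = 0,
                                 minChord = 20, maxTries = 200L, seed = 1L) {
  stopifnot(all(organSemiAxes > 0), all(vesselDiameters > 0),
            all(volumeShape >= 2))
  ny <- volumeShape[1]; nx <- volumeShape[2]; nz <- volumeShape[3]
  vs <- stats::setNames(as.numeric(voxelSize), c("y", "x", "z"))
  # voxel centres in um, organ centred at the volume centre
  cy <- (seq_len(ny) - 0.5) * vs["y"] - ny * vs["y"] / 2
  cx <- (seq_len(nx) - 0.5) * vs["x"] - nx * vs["x"] / 2
  cz <- (seq_len(nz) - 0.5) * vs["z"] - nz * vs["z"] / 2
  a <- organSemiAxes[1]; b <- organSemiAxes[2]; cc <- organSemiAxes[3]
  q2d <- outer((cy / a)^2, (cx / b)^2, "+")
  organ <- outer(q2d, (cz / cc)^2, "+") <= 1
  if (!any(organ)) stop("organ ellipsoid does not intersect the volume")

  specs <- vessels
  diams <- rep_len(vesselDiameters, max(1L, nVessels))
  if (is.null(specs)) {
    specs <- list()
    if (nVessels > 0) {
      specs <- withSeed(seed, {
        acc <- list(); tries <- 0L
        while (length(acc) < nVessels && tries < maxTries) {
          tries <- tries + 1L
          d <- diams[length(acc) + 1L]
          r <- d / 2
          # conservative inner ellipsoid: uniform scaling by
          # 1 - r/a_min keeps every point at least r from the surface
          # (the level-set gradient of the ellipsoid is at most 1/a_min)
          ash <- organSemiAxes * max(1 - r / min(organSemiAxes), 1e-6)
          # random interior point and in-plane direction
          repeat {
            p <- c(runif(1, -ash[1], ash[1]), runif(1, -ash[2], ash[2]),
                   runif(1, -0.8 * ash[3], 0.8 * ash[3]))
            if (sum((p / ash)^2) < 0.8) break
          }
          phi <- runif(1, 0, 2 * pi)
          u <- c(sin(phi), cos(phi), 0)   # (y, x, z): horizontal
          # chord of the shrunk ellipsoid along u through p
          A <- sum((u / ash)^2); B <- 2 * sum(p * u / ash^2)
          C <- sum((p / ash)^2) - 1
          disc <- B^2 - 4 * A * C
          if (disc <= 0) next
          t1 <- (-B - sqrt(disc)) / (2 * A); t2 <- (-B + sqrt(disc)) / (2 * A)
          if ((t2 - t1) < minChord) next
          p0 <- p + t1 * u; p1 <- p + t2 * u
          acc[[length(acc) + 1L]] <- list(
            p0 = c(p0[1] + ny * vs["y"] / 2, p0[2] + nx * vs["x"] / 2,
                   p0[3] + nz * vs["z"] / 2),
            p1 = c(p1[1] + ny * vs["y"] / 2, p1[2] + nx * vs["x"] / 2,
                   p1[3] + nz * vs["z"] / 2),
            diameter = d)
        }
        acc
      })
      if (length(specs) < nVessels)
        stop(sprintf("could only place %d of %d vessels within %d tries",
                     length(specs), nVessels, maxTries))
    }
  }

  vol <- array(backgroundIntensity, dim = c(ny, nx, nz))
  vol[organ] <- organIntensity
  vmask <- array(FALSE, dim = c(ny, nx, nz))
  axes <- list()
  trueD <- numeric(0)
  ycent <- (seq_len(ny) - 0.5) * vs["y"]
  xcent <- (seq_len(nx) - 0.5) * vs["x"]
  zcent <- (seq_len(nz) - 0.5) * vs["z"]
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    r <- sp$diameter / 2
    p0 <- sp$p0; p1 <- sp$p1
    lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
    iy <- which(ycent >= lo[1] & ycent <= hi[1])
    ix <- which(xcent >= lo[2] & xcent <= hi[2])
    iz <- which(zcent >= lo[3] & zcent <= hi[3])
    if (!length(iy) || !length(ix) || !length(iz)) next
    # distance from voxel centres to the 3D segment
    g <- expand.grid(y = ycent[iy], x = xcent[ix], z = zcent[iz])
    dvec <- p1 - p0
    len2 <- sum(dvec^2)
    t <- ((g$y - p0[1]) * dvec[1] + (g$x - p0[2]) * dvec[2] +
          (g$z - p0[3]) * dvec[3]) / len2
    # flat-capped cylinder: perpendicular distance within the segment span
    dd <- sqrt((g$y - (p0[1] + t * dvec[1]))^2 +
               (g$x - (p0[2] + t * dvec[2]))^2 +
               (g$z - (p0[3] + t * dvec[3]))^2)
    inside <- array(dd <= r & t >= 0 & t <= 1,
                    dim = c(length(iy), length(ix), length(iz)))
    sub <- vmask[iy, ix, iz, drop = FALSE]
    vmask[iy, ix, iz] <- sub | inside
    id <- sprintf("v%d", i)
    trueD[id] <- sp$diameter
    axpx <- rbind(c(p0[1] / vs["y"] + 0.5, p0[2] / vs["x"] + 0.5),
                  c(p1[1] / vs["y"] + 0.5, p1[2] / vs["x"] + 0.5))
    axv <- VesselAxis(axpx, id = id)
    attr(axv, "zSlice") <- mean(c(p0[3], p1[3])) / vs["z"] + 0.5
    axes[[id]] <- axv
  }
  vol[vmask] <- vesselIntensity
  if (noiseSd > 0)
    vol <- vol + withSeed(seed + 1L,
      array(rnorm(length(vol), 0, noiseSd), dim = dim(vol)))

  frac <- if (any(organ)) sum(vmask & organ) / sum(organ) else 0
  truth <- new("PhantomTruth",
               trueVelocity = numeric(0), trueDiameters = trueD,
               trueLeakFraction = numeric(0), injectedShifts = NULL,
               lumenMask = NULL, organMask = organ, vesselMask = vmask,
               trueVesselVolumeFraction = frac, vesselAxes = axes,
               seed = as.integer(seed))
  list(volume = VolumeStack(vol, voxelSize = vs), truth = truth)
}
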