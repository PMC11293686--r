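test_that("Otsu threshold equals the brute-force maximiser", {
  set.seed(31)
  for (i in 1:25) {
    vals <- switch(1 + i %% 4,
      rnorm(400, 50, 8),
      c(rnorm(300, 30, 5), rnorm(100, 120, 10)),
      runif(250, 0, 255),
      c(rexp(200, 1 / 40), rnorm(60, 200, 3)))
    expect_equal(otsuThreshold(vals), bruteOtsu(vals), tolerance = 1e-12)
  }
  expect_true(is.na(otsuThreshold(rep(3, 50))))
})

test_that("3D distance transform equals brute force on small volumes", {
  set.seed(7)
  cases <- list(
    list(dim = c(9, 9, 9), spacing = c(1, 1, 1)),
    list(dim = c(12, 10, 8), spacing = c(1, 1, 2.5)),
    list(dim = c(20, 20, 20), spacing = c(0.7, 1.3, 2)))
  for (cs in cases) {
    mask <- array(runif(prod(cs$dim)) < 0.7, cs$dim)
    got <- distanceTransform(mask, cs$spacing)
    want <- bruteEdt(mask, cs$spacing)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # all-TRUE mask: no background, infinite distances
  allIn <- array(TRUE, c(4, 4, 4))
  expect_true(all(is.infinite(distanceTransform(allIn))))
})

test_that("distance shell saturates, respects depth and sphere geometry", {
  ph <- clearedVolumePhantom(volumeShape = c(60, 60, 60),
                             voxelSize = c(10, 10, 10),
                             organSemiAxes = c(200, 200, 200),
                             nVessels = 0, seed = 1)
  organ <- new("OrganMask", mask = ph$truth@organMask,
               voxelSize = c(y = 10, x = 10, z = 10),
               provenance = "truth")
  # depth beyond the inradius: shell = organ
  deep <- distanceShell(organ, depth = 500)
  expect_identical(maskArray(deep), maskArray(organ))

  sh <- distanceShell(organ, depth = 150)
  m <- maskArray(sh)
  expect_true(all(m <= maskArray(organ)))
  # sphere of radius 200 um: centre voxel (inner 50 um core) excluded
  expect_false(m[30, 30, 30])
  # every shell voxel strictly within 150 um of the boundary
  dist <- distanceTransform(maskArray(organ), c(10, 10, 10))
  expect_true(all(dist[m] < 150))
  # downscaled fidelity mode stays inside the organ and covers the rim
  shD <- distanceShell(organ, depth = 150, fidelity = "downscaled")
  expect_true(all(maskArray(shD) <= maskArray(organ)))
  expect_gt(sum(maskArray(shD) & m) / sum(m), 0.8)
})

test_that("FOV sampling respects shell, non-overlap and seed determinism", {
  ph <- clearedVolumePhantom(volumeShape = c(100, 100, 30),
                             voxelSize = c(10, 10, 10),
                             organSemiAxes = c(420, 420, 120),
                             nVessels = 0, seed = 2)
  organ <- new("OrganMask", mask = ph$truth@organMask,
               voxelSize = c(y = 10, x = 10, z = 10),
               provenance = "truth")
  shell <- distanceShell(organ, depth = 100)
  fov <- sampleFovs(shell, n = 8, side = 120, seed = 5)
  expect_equal(nrow(fov), 8)
  m <- maskArray(shell)
  for (i in seq_len(8)) {
    f <- fov[i, ]
    # centroid voxel in shell
    iy <- round(f$centroidY / 10 + 0.5); ix <- round(f$centroidX / 10 + 0.5)
    iz <- f$zSlice
    expect_true(m[iy, ix, iz])
    expect_equal(f$sideY, 12); expect_equal(f$sideX, 12)
    for (j in seq_len(i - 1)) {
      g <- fov[j, ]
      expect_false(ThymoVasc:::rectsOverlap(
        c(f$y0, f$x0, f$sideY, f$sideX),
        c(g$y0, g$x0, g$sideY, g$sideX)))
    }
  }
  expect_identical(fov, sampleFovs(shell, n = 8, side = 120, seed = 5))
  fov2 <- sampleFovs(shell, n = 8, side = 120, seed = 6)
  expect_false(identical(fov$y0, fov2$y0))
  expect_error(sampleFovs(shell, n = 500, side = 120, seed = 1,
                          maxTries = 2000), "placed only")
})

test_that("FOV vessel area matches truth rasters and guards degenerate FOVs", {
  # symmetric bimodal half/half
  half <- cbind(matrix(10, 40, 20), matrix(200, 40, 20))
  expect_equal(fovVesselArea(half)$percent, 50)

  # constructed vessel raster: band through the FOV, light blur + noise
  set.seed(41)
  img <- matrix(40, 96, 96); img[45:54, ] <- 200
  truthFrac <- 100 * 10 / 96
  img <- ThymoVasc:::gblur2d(img, 1) + matrix(rnorm(96 * 96, 0, 3), 96, 96)
  a <- fovVesselArea(img)
  expect_lt(abs(a$percent - truthFrac), 2)

  # organ-only FOV with noise: no separable vessel structure -> 0%
  set.seed(42)
  noiseFov <- matrix(40, 48, 48) + matrix(rnorm(48 * 48, 0, 3), 48, 48)
  expect_equal(fovVesselArea(noiseFov)$percent, 0)
  expect_warning(out <- fovVesselArea(matrix(7, 20, 20)), "constant")
  expect_equal(out$percent, 0)

  # intensity rescaling leaves the area unchanged
  b <- fovVesselArea(img * 12 + 100)
  expect_equal(a$percent, b$percent, tolerance = 1e-9)
})

test_that("vessel counting uses 8-connectivity with a minimum-size filter", {
  m <- matrix(FALSE, 40, 40)
  m[5:10, ] <- TRUE          # tube crossing the FOV
  m[25:30, ] <- TRUE         # second, disjoint tube
  expect_equal(countVesselsInFov(m, pixelSize = 1), 2L)
  expect_equal(countVesselsInFov(matrix(FALSE, 10, 10)), 0L)
  # diagonal touching joins components
  dg <- matrix(FALSE, 10, 10); dg[3, 3] <- TRUE; dg[4, 4] <- TRUE
  expect_equal(countVesselsInFov(dg, minArea = 1), 1L)
  # speckle below the size filter is ignored
  sp <- m; sp[18, 18] <- TRUE
  expect_equal(countVesselsInFov(sp, pixelSize = 1), 2L)
  # k non-touching phantom vessels count as k
  ph <- clearedVolumePhantom(
    volumeShape = c(120, 120, 20), voxelSize = c(1, 1, 1),
    organSemiAxes = c(55, 55, 9),
    vessels = list(
      list(p0 = c(30, 10, 10), p1 = c(30, 110, 10), diameter = 6),
      list(p0 = c(60, 10, 10), p1 = c(60, 110, 10), diameter = 6),
      list(p0 = c(90, 10, 10), p1 = c(90, 110, 10), diameter = 6)),
    noiseSd = 0, seed = 1)
  sl <- ph$truth@vesselMask[, , 10]
  expect_equal(countVesselsInFov(sl, pixelSize = 1), 3L)
})

test_that("vessel frequency follows count / organ area", {
  expect_equal(fovVesselFrequency(5, 0.09), 55.6, tolerance = 1e-3)
  expect_equal(fovVesselFrequency(5, 0.045), 111.1, tolerance = 1e-3)
  expect_equal(fovVesselFrequency(0, 0.09), 0)
  expect_error(fovVesselFrequency(3, 0), "positive")
})

test_that("organ segmentation recovers the phantom mask", {
  ph <- clearedVolumePhantom(volumeShape = c(96, 96, 24),
                             voxelSize = c(2, 2, 4),
                             organSemiAxes = c(80, 80, 40),
                             nVessels = 4, vesselDiameters = 10,
                             noiseSd = 0, seed = 3)
  pre <- preprocessVolume(ph$volume)
  om <- segmentOrganMask(pre, method = "threshold")
  truth <- ph$truth@organMask
  d2 <- dim(maskArray(om))
  trd <- array(FALSE, d2)
  for (k in seq_len(d2[3]))
    trd[, , k] <- ThymoVasc:::blockDownscale2(truth[, , k] * 1) >= 0.5
  dice <- 2 * sum(maskArray(om) & trd) / (sum(maskArray(om)) + sum(trd))
  expect_gte(dice, 0.95)

  # manual polygons rasterise exactly
  vol <- VolumeStack(array(0, c(20, 20, 2)), c(1, 1, 1))
  poly <- rbind(c(4.5, 4.5), c(4.5, 15.5), c(15.5, 15.5), c(15.5, 4.5))
  omM <- segmentOrganMask(vol, method = "manual",
                          polygons = list(poly, NULL))
  want <- array(FALSE, c(20, 20, 2)); want[5:15, 5:15, 1] <- TRUE
  expect_identical(maskArray(omM), want)

  expect_error(segmentOrganMask(VolumeStack(array(1, c(16, 16, 4))),
                                method = "threshold"), "empty")
})

test_that("full morphometry chain recovers diameter and area fraction", {
  cb <- capillaryBedPhantom(seed = 5)
  res <- suppressWarnings(runMorphometry(
    cb$ph$volume, vesselAxes = cb$horizontalAxes, shellDepth = 40,
    nFov = 10, fovSide = 60, seed = 4, crossHalfLength = 14))
  expect_equal(res$summary$nFov, 10)
  expect_lt(abs(res$summary$meanDiameterUm - 8) / 8, 0.10)
  expect_lt(abs(res$summary$meanAreaPercent -
                100 * cb$ph$truth@trueVesselVolumeFraction), 3)
  # chain invariants asserted on the run itself
  expect_true(all(maskArray(res$shellMask) <= maskArray(res$organMask)))
  expect_true(all(res$fovTable$sideY == res$fovTable$sideY[1]))
})

test_that("morphometry runs are seed-deterministic and order vessel calibres", {
  gen <- function(diam, seed)
    clearedVolumePhantom(volumeShape = c(224, 224, 40),
                         voxelSize = c(0.5, 0.5, 1),
                         organSemiAxes = c(50, 50, 18), nVessels = 6,
                         vesselDiameters = diam, vesselIntensity = 200,
                         organIntensity = 40, backgroundIntensity = 5,
                         noiseSd = 3, minChord = 30, seed = seed)
  ph <- gen(7, 21)
  run <- function(p) suppressWarnings(runMorphometry(
    p$volume, vesselAxes = p$truth@vesselAxes, shellDepth = 40,
    nFov = 4, fovSide = 24, seed = 2, crossHalfLength = 10))
  res <- run(ph)
  expect_identical(res$fovTable, run(ph)$fovTable)

  phW <- gen(10, 21)
  resW <- run(phW)
  expect_gt(resW$summary$meanDiameterUm, res$summary$meanDiameterUm)
})
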