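test_that("cross-lines are equidistant, perpendicular and bounded", {
  img <- matrix(0, 64, 128)
  ax <- VesselAxis(rbind(c(32, 10), c(32, 110)))   # arc length 100
  cls <- placeCrossLines(img, ax, spacing = 10, halfLength = 10)
  expect_equal(nrow(cls@profiles), 11)             # floor(100/10) + 1
  expect_true(all(abs(abs(cls@directions[, 1]) - 1) < 1e-9))
  expect_true(all(abs(cls@directions[, 2]) < 1e-9))

  # circular arc: |dot(direction, tangent)| < 0.05 against analytic tangents
  th <- seq(0, pi / 2, length.out = 80)
  arc <- cbind(60 - 40 * sin(th), 20 + 40 * cos(th))
  axArc <- VesselAxis(arc)
  clsArc <- placeCrossLines(matrix(0, 80, 80), axArc, spacing = 5,
                            halfLength = 4)
  pp <- ThymoVasc:::distanceToPolyline(clsArc@centers, arc)
  sA <- pp$arc / 40
  tanA <- cbind(-cos(sA + 0), -sin(sA))  # d/ds of (60-40sin, 20+40cos)
  dots <- abs(rowSums(clsArc@directions * tanA))
  expect_true(all(dots < 0.05))

  # out-of-bounds lines dropped with warning
  expect_warning(placeCrossLines(matrix(0, 20, 128),
                 VesselAxis(rbind(c(4, 10), c(4, 110))), spacing = 10,
                 halfLength = 10), "dropped")
})

test_that("profileFwhm matches top-hat and Gaussian closed forms", {
  # top-hat of plateau width 11 px
  prof <- c(rep(0, 20), rep(10, 11), rep(0, 20))
  expect_equal(profileFwhm(prof, 1), 11, tolerance = 1 / 11)

  # Gaussian sigma = 4 px: FWHM = 2.3548 * 4 = 9.42 px within 2%
  u <- seq(-30, 30)
  g <- exp(-u^2 / (2 * 16))
  expect_equal(profileFwhm(g, 1), 2 * sqrt(2 * log(2)) * 4,
               tolerance = 0.02)
  # in micrometres
  expect_equal(profileFwhm(g, 0.31), 0.31 * 2 * sqrt(2 * log(2)) * 4,
               tolerance = 0.02)

  expect_error(profileFwhm(rep(5, 40)), "no vessel signal")
  # clipped profile: monotone ramp never recrosses the half level
  expect_error(profileFwhm(seq(5, 10, length.out = 31)), "wider")
  # interior dip does not truncate the width (outermost crossing rule)
  dip <- c(rep(0, 15), rep(10, 6), 2, 2, rep(10, 6), rep(0, 15))
  expect_equal(profileFwhm(dip, 1), 14, tolerance = 0.1)
})

test_that("cross-line diameter recovers tube truth at any orientation", {
  for (d in c(8, 14)) {
    t0 <- makeTube(diameterPx = d, angleDeg = 0)
    est0 <- measureVesselDiameter(t0$image, t0$axis, spacing = 2,
                                  halfLength = 24, pixelSize = 1)
    expect_lt(abs(diameter(est0) - d), 0.5)
    t37 <- makeTube(diameterPx = d, angleDeg = 37)
    est37 <- suppressWarnings(
      measureVesselDiameter(t37$image, t37$axis, spacing = 2,
                            halfLength = 24, pixelSize = 1))
    expect_lt(abs(diameter(est37) - diameter(est0)), 0.5)
  }

  # linear taper 6 -> 10 px: mean ~ 8 px
  tp <- makeTaperTube(d0 = 6, d1 = 10)
  estT <- measureVesselDiameter(tp$image, tp$axis, spacing = 2,
                                halfLength = 16, pixelSize = 1)
  expect_lt(abs(diameter(estT) - 8), 0.5)

  expect_error(measureVesselDiameter(matrix(5, 40, 40),
               VesselAxis(rbind(c(20, 5), c(20, 35))), halfLength = 10,
               pixelSize = 1), "usable")
})

test_that("diameter is invariant to intensity scale and insensitive to spacing", {
  t0 <- makeTube(diameterPx = 10, angleDeg = 20)
  e1 <- measureVesselDiameter(t0$image, t0$axis, spacing = 4,
                              halfLength = 20, pixelSize = 1)
  e2 <- measureVesselDiameter(t0$image * 7.3, t0$axis, spacing = 4,
                              halfLength = 20, pixelSize = 1)
  expect_equal(diameter(e1), diameter(e2), tolerance = 1e-9)
  eHalf <- measureVesselDiameter(t0$image, t0$axis, spacing = 2,
                                 halfLength = 20, pixelSize = 1)
  expect_lt(abs(diameter(eHalf) - diameter(e1)) / diameter(e1), 0.02)
})

test_that("manual single-line mode matches the cross-line estimate", {
  t0 <- makeTube(diameterPx = 12, angleDeg = 0)
  # perpendicular manual line across the tube centre
  man <- measureManualDiameter(t0$image, rbind(c(18, 48), c(78, 48)),
                               pixelSize = 1)
  expect_lt(abs(diameter(man) - 12), 0.5)
  expect_equal(man@method, "manual")
  cl <- measureVesselDiameter(t0$image, t0$axis, spacing = 2,
                              halfLength = 24, pixelSize = 1)
  expect_lt(abs(diameter(man) - diameter(cl)), 0.5)

  expect_error(measureManualDiameter(t0$image,
               rbind(c(10, 10), c(10, 10)), 1), "degenerate")
  expect_error(measureManualDiameter(matrix(4, 40, 40),
               rbind(c(5, 5), c(35, 35)), 1), "no vessel signal")
  expect_error(measureManualDiameter(t0$image,
               rbind(c(-3, 5), c(35, 35)), 1), "outside")
})
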