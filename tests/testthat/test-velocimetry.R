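test_that("kymograph sampling reflects motion and orientation", {
  ph <- quickFlow(trueVelocity = 0, noiseSd = 0, rbcCount = 2, nFrames = 8)
  ky <- extractKymograph(ph$movie, ph$truth@vesselAxes[[1]])
  for (t in 2:8) expect_equal(ky@data[t, ], ky@data[1, ])

  # reversed axis mirrors the kymograph left-right
  ax <- ph$truth@vesselAxes[[1]]
  rev <- VesselAxis(axisCoords(ax)[2:1, ])
  ky2 <- extractKymograph(ph$movie, rev)
  expect_equal(ky2@data[1, ], base::rev(ky@data[1, ]), tolerance = 1e-6)

  expect_error(extractKymograph(ph$movie,
               VesselAxis(rbind(c(24, 10), c(24, 12)))), "shorter")
})

test_that("kymograph velocity recovers truth, zero flow and time reversal", {
  ph <- flowPhantom(imageShape = c(48, 340), nFrames = 20,
                    trueVelocity = 200, frameRate = 30,
                    vesselAxis = rbind(c(24, 10), c(24, 330)),
                    rbcCount = 4, noiseSd = 3, seed = 6)
  ky <- extractKymograph(ph$movie, ph$truth@vesselAxes[[1]])
  est <- estimateVelocityKymograph(ky)
  expect_equal(velocity(est), 200, tolerance = 0.05)

  # stationary cells: vertical streaks, zero velocity
  ph0 <- quickFlow(trueVelocity = 0, noiseSd = 1, rbcCount = 3, seed = 2)
  ky0 <- extractKymograph(ph0$movie, ph0$truth@vesselAxes[[1]])
  expect_lt(abs(velocity(estimateVelocityKymograph(ky0))), 3)

  # time reversal negates the estimate
  kyR <- new("Kymograph", data = ky@data[nrow(ky@data):1, ],
             pixelSize = ky@pixelSize, frameRate = ky@frameRate,
             axisId = ky@axisId)
  expect_equal(velocity(estimateVelocityKymograph(kyR)),
               -velocity(est), tolerance = 0.02)

  # blank kymograph: no flow structure
  blank <- new("Kymograph", data = matrix(5, 12, 60), pixelSize = 0.31,
               frameRate = 30, axisId = "x")
  expect_error(estimateVelocityKymograph(blank), "no measurable flow")
  expect_error(estimateVelocityKymograph(
    new("Kymograph", data = matrix(rnorm(4 * 60), 4, 60),
        pixelSize = 0.31, frameRate = 30, axisId = "x")), "8 rows")
})

test_that("RBC detection finds dark blobs at subpixel accuracy", {
  lumen <- matrix(TRUE, 80, 120)
  img <- matrix(100, 80, 120)
  expect_equal(nrow(detectRbcCentroids(img, lumen)), 0)

  addDisk <- function(im, cy, cx, depth = 70, sigma = 3) {
    yy <- matrix(seq_len(nrow(im)), nrow(im), ncol(im))
    xx <- matrix(rep(seq_len(ncol(im)), each = nrow(im)), nrow(im),
                 ncol(im))
    im - depth * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sigma^2))
  }
  one <- addDisk(img, 40, 60)
  c1 <- detectRbcCentroids(one, lumen)
  expect_equal(nrow(c1), 1)
  expect_lt(sqrt(sum((c1[1, ] - c(40, 60))^2)), 0.5)

  two <- addDisk(addDisk(img, 25, 30), 55, 90)
  c2 <- detectRbcCentroids(two, lumen)
  expect_equal(nrow(c2), 2)
  got <- c2[order(c2[, 1]), ]
  expect_lt(max(abs(got - rbind(c(25, 30), c(55, 90)))), 0.5)

  expect_error(detectRbcCentroids(img, matrix(FALSE, 80, 120)), "empty")
})

test_that("tracking velocimetry matches the displacement arithmetic", {
  # blob advancing 3.0 px/frame at 0.31 um/px, 60 fps -> 55.8 um/s
  ph <- quickFlow(trueVelocity = 55.8, frameRate = 60, noiseSd = 0,
                  rbcCount = 2, seed = 5)
  est <- trackRbcVelocity(ph$movie, ph$truth@vesselAxes[[1]],
                          ph$truth@lumenMask, vMax = 300)
  expect_equal(velocity(est), 55.8, tolerance = 0.01)
  expect_equal(est@method, "tracking")

  ph0 <- quickFlow(trueVelocity = 0, noiseSd = 0, rbcCount = 2, seed = 5)
  est0 <- trackRbcVelocity(ph0$movie, ph0$truth@vesselAxes[[1]],
                           ph0$truth@lumenMask, vMax = 300)
  expect_equal(velocity(est0), 0, tolerance = 1e-6)

  noCells <- quickFlow(trueVelocity = 100, noiseSd = 0, rbcCount = 0)
  expect_error(trackRbcVelocity(noCells$movie,
               noCells$truth@vesselAxes[[1]], noCells$truth@lumenMask),
               "no trackable cells")
})

test_that("velocity estimates scale with calibration metadata and agree across methods", {
  ph <- quickFlow(trueVelocity = 150, frameRate = 60, noiseSd = 3,
                  rbcCount = 3, nFrames = 20, seed = 11)
  ax <- ph$truth@vesselAxes[[1]]
  vK <- velocity(estimateVelocityKymograph(extractKymograph(ph$movie, ax)))
  vT <- velocity(trackRbcVelocity(ph$movie, ax, ph$truth@lumenMask,
                                  vMax = 600))
  expect_equal(vK, 150, tolerance = 0.05)
  expect_equal(vT, 150, tolerance = 0.05)
  expect_lt(abs(vK - vT) / abs(vT), 0.10)

  # same pixel data, doubled frame rate metadata -> doubled velocity
  fast <- FlowMovie(frames(ph$movie), pixelSize = 0.31, frameRate = 120)
  expect_equal(velocity(estimateVelocityKymograph(
    extractKymograph(fast, ax))), 2 * vK, tolerance = 1e-6)
  wide <- FlowMovie(frames(ph$movie), pixelSize = 0.62, frameRate = 60)
  expect_equal(velocity(trackRbcVelocity(wide, ax, ph$truth@lumenMask,
                                         vMax = 1200)), 2 * vT,
               tolerance = 1e-6)

  # noise-free phantom: methods agree within 2%
  ph2 <- quickFlow(trueVelocity = 120, frameRate = 60, noiseSd = 0,
                   rbcCount = 3, nFrames = 20, seed = 12)
  vK2 <- velocity(estimateVelocityKymograph(
    extractKymograph(ph2$movie, ax)))
  vT2 <- velocity(trackRbcVelocity(ph2$movie, ax, ph2$truth@lumenMask,
                                   vMax = 600))
  expect_lt(abs(vK2 - vT2) / abs(vT2), 0.02)
})

test_that("reversing the frame order negates both estimators", {
  ph <- quickFlow(trueVelocity = 130, frameRate = 60, noiseSd = 2,
                  rbcCount = 3, nFrames = 16, seed = 13)
  ax <- ph$truth@vesselAxes[[1]]
  rev <- FlowMovie(frames(ph$movie)[, , 16:1], pixelSize = 0.31,
                   frameRate = 60)
  vK <- velocity(estimateVelocityKymograph(extractKymograph(ph$movie, ax)))
  vKr <- velocity(estimateVelocityKymograph(extractKymograph(rev, ax)))
  expect_equal(vKr, -vK, tolerance = 0.02)
  vT <- velocity(trackRbcVelocity(ph$movie, ax, ph$truth@lumenMask,
                                  vMax = 600))
  vTr <- velocity(trackRbcVelocity(rev, ax, ph$truth@lumenMask,
                                   vMax = 600))
  expect_equal(vTr, -vT, tolerance = 0.02)
})
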