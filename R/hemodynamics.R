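# Shear rate and Evans-blue leakage.
#
# Wall shear rate uses the Poiseuille approximation 8 * velocity /
# diameter, the standard microvessel estimate when only centreline
# velocity and diameter are measured. Leakage is the ratio of mean
# intensity in a field of view immediately adjacent to a vessel
# (extravascular) over a field of view at the vessel centre
# (intravascular), computed on a frame-averaged image; dye escaping the
# vessel raises the ratio, so leakier vessels score higher.

# A rectangle is c(y0, x0, height, width) in px, covering rows
# y0 .. y0 + height - 1 and the analogous columns.
rectPixels <- function(img, rect) {
  y <- rect[1]:(rect[1] + rect[3] - 1)
  x <- rect[2]:(rect[2] + rect[4] - 1)
  if (min(y) < 1 || max(y) > nrow(img) || min(x) < 1 || max(x) > ncol(img))
    stop("FOV outside image")
  img[y, x, drop = FALSE]
}

rectsOverlap <- function(a, b) {
  ya <- c(a[1], a[1] + a[3] - 1); xa <- c(a[2], a[2] + a[4] - 1)
  yb <- c(b[1], b[1] + b[3] - 1); xb <- c(b[2], b[2] + b[4] - 1)
  ya[1] <= yb[2] && yb[1] <= ya[2] && xa[1] <= xb[2] && xb[1] <= xa[2]
}

#' Poiseuille wall shear rate
#'
#' `shear = 8 * |velocity| / diameter`, in 1/s when velocity is in um/s
#' and diameter in um. The sign of the flow is retained in the velocity
#' field of the result, not in the shear magnitude.
#'
#' @param velocity signed micrometres per second.
#' @param diameter micrometres (> 0).
#' @param roi vessel identifier.
#' @return A [ShearRateEstimate-class].
#' @export
shearRate <- function(velocity, diameter, roi = "") {
  if (diameter <= 0) stop("diameter must be positive")
  new("ShearRateEstimate", shearRate = 8 * abs(velocity) / diameter,
      velocity = velocity, diameter = diameter, roi = roi)
}

#' Evans-blue leakage ratio
#'
#' Ratio of the mean intensity of a field of view immediately adjacent to
#' the vessel over the mean of a field of view at the vessel centre, on a
#' frame-averaged image. The extravascular mean is the numerator: dye
#' leaking out of the vessel drives the ratio up.
#'
#' @param averagedImage numeric matrix, typically from [averageFrames()]
#'   (30-frame average by convention).
#' @param vesselFov rectangle c(y0, x0, height, width) px at the vessel
#'   centre (intravascular).
#' @param adjacentFov same-shape rectangle immediately adjacent to the
#'   vessel (extravascular). The two must not overlap.
#' @param framesAveraged number of frames averaged into `averagedImage`
#'   (metadata, default 30).
#' @return A [LeakageMeasurement-class].
#' @export
leakageRatio <- function(averagedImage, vesselFov, adjacentFov,
                         framesAveraged = 30L) {
  if (rectsOverlap(vesselFov, adjacentFov)) stop("FOVs overlap")
  intra <- mean(rectPixels(averagedImage, vesselFov))
  extra <- mean(rectPixels(averagedImage, adjacentFov))
  if (intra <= 0) stop("intravascular mean must be positive")
  new("LeakageMeasurement", ratio = extra / intra,
      intravascularMean = intra, extravascularMean = extra,
      vesselFov = as.numeric(vesselFov),
      adjacentFov = as.numeric(adjacentFov),
      framesAveraged = as.integer(framesAveraged))
}
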