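# Vessel diameter by cross-line FWHM.
#
# Equidistant lines perpendicular to the centreline are placed along a
# vessel axis; each line's intensity profile is reduced to a full width at
# half maximum, and the vessel diameter is the mean of the per-line
# widths. A single-line "manual" mode measures one user-given line with
# the same width rule.
#
# Width rule: background is the lower of the two tail means (outer 10% of
# samples at each end); the half level is background + (peak -
# background)/2; the width spans the OUTERMOST half-level crossings
# bracketing the global peak, each located by linear interpolation.
# Taking the outermost (not innermost) crossings keeps intraluminal dips
# from negative-contrast cells from truncating the width.

#' CrossLineSet: perpendicular cross-lines along an axis
#'
#' @slot centers `m x 2` (y, x) px positions on the axis.
#' @slot directions `m x 2` unit vectors perpendicular to the local
#'   tangent.
#' @slot halfLength half line length, px.
#' @slot profiles `m x (2*halfLength + 1)` sampled intensities (unit
#'   spacing).
#' @slot nDroppedOutOfBounds lines discarded for leaving the image.
#' @aliases CrossLineSet
#' @exportClass CrossLineSet
setClass("CrossLineSet",
  representation(centers = "matrix", directions = "matrix",
                 halfLength = "numeric", profiles = "matrix",
                 nDroppedOutOfBounds = "integer"))

#' Place perpendicular cross-lines along a vessel axis
#'
#' Centres are spaced every `spacing` px of arc length starting at the
#' first vertex (an axis of arc length L yields floor(L/spacing) + 1
#' lines). Directions are unit normals of finite-difference tangents;
#' profiles are sampled at unit spacing by bilinear interpolation. Lines
#' with any sample outside the image are dropped with a warning.
#'
#' @param image numeric matrix `[y, x]`.
#' @param axis a [VesselAxis-class].
#' @param spacing px between line centres (default 2).
#' @param halfLength half line length, px.
#' @return A [CrossLineSet-class].
#' @export
placeCrossLines <- function(image, axis, spacing = 2, halfLength = 15) {
  ax <- axisCoords(axis)
  L <- polyArcLength(ax)
  if (L < spacing) stop("axis arc length shorter than spacing")
  s <- seq(0, L, by = spacing)
  par <- polylineAt(ax, s)
  tans <- par$tangents
  norms <- cbind(-tans[, 2], tans[, 1])
  offs <- seq(-halfLength, halfLength)
  nr <- nrow(image); nc <- ncol(image)
  keep <- logical(length(s))
  profs <- matrix(NA_real_, length(s), length(offs))
  for (i in seq_along(s)) {
    py <- par$points[i, 1] + offs * norms[i, 1]
    px <- par$points[i, 2] + offs * norms[i, 2]
    if (any(py < 1 | py > nr | px < 1 | px > nc)) next
    keep[i] <- TRUE
    profs[i, ] <- bilinearSample(image, py, px)
  }
  if (any(!keep))
    warning(sprintf("%d cross-line(s) dropped: outside image bounds",
                    sum(!keep)))
  new("CrossLineSet", centers = par$points[keep, , drop = FALSE],
      directions = norms[keep, , drop = FALSE], halfLength = halfLength,
      profiles = profs[keep, , drop = FALSE],
      nDroppedOutOfBounds = sum(!keep))
}

#' Full width at half maximum of an intensity profile
#'
#' @param profile numeric vector sampled at unit (pixel) spacing.
#' @param pixelSize micrometres per pixel (default 1: width in px).
#' @return Width in micrometres (or px if `pixelSize = 1`).
#' @export
profileFwhm <- function(profile, pixelSize = 1) {
  n <- length(profile)
  if (n < 5) stop("profile too short")
  k <- max(1L, floor(0.1 * n))
  bg <- min(mean(profile[seq_len(k)]), mean(profile[n - seq_len(k) + 1]))
  m <- which.max(profile)
  pk <- profile[m]
  if (pk - bg <= max(1e-12, 1e-9 * max(abs(profile), 1)))
    stop("no vessel signal")
  half <- bg + (pk - bg) / 2
  # outermost upward crossing left of the peak
  xL <- NA_real_
  if (profile[1] >= half) stop("vessel wider than cross-line")
  for (i in seq_len(m - 1)) {
    if (profile[i] < half && profile[i + 1] >= half) {
      xL <- i + (half - profile[i]) / (profile[i + 1] - profile[i])
      break
    }
  }
  if (profile[n] >= half) stop("vessel wider than cross-line")
  xR <- NA_real_
  for (i in seq(n - 1, m)) {
    if (profile[i + 1] < half && profile[i] >= half) {
      xR <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
      break
    }
  }
  if (is.na(xL) || is.na(xR)) stop("no vessel signal")
  (xR - xL) * pixelSize
}

#' Measure vessel diameter by cross-line FWHM
#'
#' Places cross-lines along the axis, reduces each to an FWHM, excludes
#' lines with no measurable width, and reports the mean width as the
#' vessel diameter. At least 3 usable lines are required.
#'
#' @inheritParams placeCrossLines
#' @param pixelSize micrometres per pixel.
#' @param roi vessel identifier recorded in the result.
#' @return A [DiameterEstimate-class] with method "crossline".
#' @export
measureVesselDiameter <- function(image, axis, spacing = 2,
                                  halfLength = NULL, pixelSize = 0.31,
                                  roi = NULL) {
  if (is.null(halfLength))
    halfLength <- max(8, round(min(dim(image)) / 4))
  if (is.null(roi)) roi <- axis@id
  cls <- placeCrossLines(image, axis, spacing = spacing,
                         halfLength = halfLength)
  widths <- numeric(0)
  dropped <- cls@nDroppedOutOfBounds
  for (i in seq_len(nrow(cls@profiles))) {
    w <- tryCatch(profileFwhm(cls@profiles[i, ], pixelSize),
                  error = function(e) NA_real_)
    if (is.na(w)) dropped <- dropped + 1L else widths <- c(widths, w)
  }
  if (length(widths) < 3)
    stop("fewer than 3 usable cross-lines")
  new("DiameterEstimate", diameter = mean(widths), perLineWidths = widths,
      nLines = length(widths), nDropped = as.integer(dropped),
      method = "crossline", roi = roi)
}

#' Measure vessel diameter along a single manual line
#'
#' Samples one straight line between the given endpoints at unit spacing
#' and applies the same FWHM rule; the counterpart of drawing a
#' straight-line profile by hand across a vessel.
#'
#' @param image numeric matrix `[y, x]`.
#' @param endpoints `2 x 2` matrix, rows = (y, x) line endpoints in px.
#' @param pixelSize micrometres per pixel.
#' @param roi vessel identifier.
#' @return A [DiameterEstimate-class] with method "manual".
#' @export
measureManualDiameter <- function(image, endpoints, pixelSize = 0.31,
                                  roi = "manual") {
  endpoints <- as.matrix(endpoints)
  stopifnot(nrow(endpoints) == 2, ncol(endpoints) == 2)
  len <- sqrt(sum((endpoints[2, ] - endpoints[1, ])^2))
  if (len < .Machine$double.eps) stop("degenerate line: endpoints identical")
  nr <- nrow(image); nc <- ncol(image)
  if (any(endpoints[, 1] < 1 | endpoints[, 1] > nr |
          endpoints[, 2] < 1 | endpoints[, 2] > nc))
    stop("endpoints outside image")
  nSamp <- max(5L, ceiling(len) + 1L)
  tt <- seq(0, 1, length.out = nSamp)
  py <- endpoints[1, 1] + tt * (endpoints[2, 1] - endpoints[1, 1])
  px <- endpoints[1, 2] + tt * (endpoints[2, 2] - endpoints[1, 2])
  prof <- bilinearSample(image, py, px)
  step <- len / (nSamp - 1)
  w <- profileFwhm(prof, pixelSize * step)
  new("DiameterEstimate", diameter = w, perLineWidths = w, nLines = 1L,
      nDropped = 0L, method = "manual", roi = roi)
}
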