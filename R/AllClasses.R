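#' @import methods
#' @importFrom stats median pnorm quantile rnorm runif sd shapiro.test
#'   t.test var complete.cases
#' @importFrom utils combn write.csv read.csv
#' @useDynLib ThymoVasc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

setClassUnion("arrayOrNULL", c("array", "matrix", "NULL"))

#' FlowMovie: a time-lapse intravital movie
#'
#' Container for one channel of a two-photon time-lapse recording. Frames
#' are stored as a numeric array indexed `[y, x, t]` (row = y, col = x,
#' 1-based). Physical calibration is carried as pixel pitch (micrometres
#' per pixel) and frame rate (frames per second).
#'
#' @slot frames numeric array `[y, x, t]` of intensities (arbitrary units).
#' @slot pixelSize micrometres per pixel.
#' @slot frameRate frames per second.
#' @slot channel free-text channel label (e.g. "evans-blue").
#' @aliases FlowMovie
#' @exportClass FlowMovie
setClass("FlowMovie",
  representation(frames = "array", pixelSize = "numeric",
                 frameRate = "numeric", channel = "character"),
  validity = function(object) {
    if (length(dim(object@frames)) != 3) return("frames must be [y, x, t]")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    if (object@frameRate <= 0) return("frameRate must be positive")
    TRUE
  })

#' Construct a FlowMovie
#'
#' @param frames numeric array `[y, x, t]`.
#' @param pixelSize micrometres per pixel (default 0.31, the calibration of
#'   the video-rate two-photon system the package models).
#' @param frameRate frames per second (30, 60 or 120 in the modelled
#'   acquisitions; any positive value is accepted).
#' @param channel channel label.
#' @return A [FlowMovie-class] object.
#' @export
FlowMovie <- function(frames, pixelSize = 0.31, frameRate = 60,
                      channel = "evans-blue") {
  new("FlowMovie", frames = frames, pixelSize = pixelSize,
      frameRate = frameRate, channel = channel)
}

#' VolumeStack: a 3D cleared-organ intensity volume
#'
#' Voxels are stored `[y, x, z]`; `voxelSize` is a named numeric
#' `c(y=, x=, z=)` in micrometres, allowing anisotropic sampling (z is
#' typically coarser than y/x in cleared-organ stacks).
#'
#' @slot voxels numeric array `[y, x, z]`.
#' @slot voxelSize named numeric, micrometres per voxel along y, x, z.
#' @aliases VolumeStack
#' @exportClass VolumeStack
setClass("VolumeStack",
  representation(voxels = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3) return("voxels must be [y, x, z]")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
      return("voxelSize must be three positive values (y, x, z)")
    TRUE
  })

#' Construct a VolumeStack
#' @param voxels numeric array `[y, x, z]`.
#' @param voxelSize numeric length 3, micrometres per voxel along y, x, z.
#' @return A [VolumeStack-class] object.
#' @export
VolumeStack <- function(voxels, voxelSize = c(y = 1, x = 1, z = 2)) {
  voxelSize <- stats::setNames(as.numeric(voxelSize), c("y", "x", "z"))
  new("VolumeStack", voxels = voxels, voxelSize = voxelSize)
}

#' VesselAxis: an ordered centreline polyline
#'
#' An ordered polyline of `(y, x)` pixel coordinates following a vessel
#' centreline. Orientation matters: positive velocities point from the
#' first vertex towards the last.
#'
#' @slot coords numeric matrix `n x 2`, columns (y, x) in pixels.
#' @slot id vessel identifier.
#' @aliases VesselAxis
#' @exportClass VesselAxis
setClass("VesselAxis",
  representation(coords = "matrix", id = "character"),
  validity = function(object) {
    if (ncol(object@coords) != 2) return("coords must be n x 2 (y, x)")
    if (nrow(object@coords) < 2) return("axis needs at least 2 vertices")
    TRUE
  })

#' Construct a VesselAxis
#' @param coords numeric `n x 2` matrix of (y, x) pixel coordinates.
#' @param id vessel identifier.
#' @return A [VesselAxis-class] object.
#' @export
VesselAxis <- function(coords, id = "v1") {
  new("VesselAxis", coords = as.matrix(coords), id = id)
}

#' PhantomTruth: ground truth of a synthetic phantom
#'
#' Record of every quantity a phantom generator fixed by construction, so
#' downstream estimators can be scored against known truth. Slots not
#' meaningful for a given phantom kind are left empty/NULL.
#'
#' @slot trueVelocity micrometres per second (flow phantoms).
#' @slot trueDiameters named numeric, vessel id to diameter in micrometres.
#' @slot trueLeakFraction dimensionless extravascular leak fraction.
#' @slot injectedShifts `n x 2` matrix of per-frame (dy, dx) pixel shifts.
#' @slot lumenMask logical matrix, in-lumen pixels (flow phantoms).
#' @slot organMask logical array, organ voxels (volume phantoms).
#' @slot vesselMask logical array, vessel voxels (volume phantoms).
#' @slot trueVesselVolumeFraction vessel voxels / organ voxels.
#' @slot vesselAxes list of [VesselAxis-class] (plus a z attribute for 3D
#'   phantoms, in voxel units of the generated volume).
#' @slot seed integer seed the generator used.
#' @aliases PhantomTruth
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(trueVelocity = "numeric", trueDiameters = "numeric",
                 trueLeakFraction = "numeric", injectedShifts = "arrayOrNULL",
                 lumenMask = "arrayOrNULL", organMask = "arrayOrNULL",
                 vesselMask = "arrayOrNULL",
                 trueVesselVolumeFraction = "numeric",
                 vesselAxes = "list", seed = "integer"))

#' AlignmentResult: rigid frame alignment of a movie
#'
#' @slot alignedMovie the translated [FlowMovie-class].
#' @slot shifts `n x 2` estimated per-frame content shifts (dy, dx) px,
#'   relative to the reference frame; the reference row is (0, 0).
#' @slot referenceIndex index of the reference frame.
#' @slot lowConfidence logical per frame; TRUE where the correlation peak
#'   was too weak to trust (featureless frames report shift (0, 0)).
#' @aliases AlignmentResult
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(alignedMovie = "FlowMovie", shifts = "matrix",
                 referenceIndex = "integer", lowConfidence = "logical"),
  validity = function(object) {
    n <- dim(object@alignedMovie@frames)[3]
    if (nrow(object@shifts) != n) return("one shift per frame required")
    r <- object@referenceIndex
    if (r < 1 || r > n) return("referenceIndex out of range")
    if (any(object@shifts[r, ] != 0))
      return("reference frame shift must be (0, 0)")
    TRUE
  })

#' Kymograph: space-time sampling along a vessel axis
#'
#' @slot data numeric matrix, rows = time (frames), cols = arc-length
#'   position along the axis (unit pixel spacing).
#' @slot pixelSize micrometres per pixel.
#' @slot frameRate frames per second.
#' @slot axisId vessel axis identifier.
#' @aliases Kymograph
#' @exportClass Kymograph
setClass("Kymograph",
  representation(data = "matrix", pixelSize = "numeric",
                 frameRate = "numeric", axisId = "character"))

#' VelocityEstimate: per-vessel blood-flow velocity
#'
#' @slot velocity signed micrometres per second (positive = along the axis
#'   orientation).
#' @slot method "kymograph" or "tracking".
#' @slot nObservations streak lines or tracked links used.
#' @slot dispersion SD across observations, micrometres per second.
#' @slot roi vessel/axis identifier.
#' @aliases VelocityEstimate
#' @exportClass VelocityEstimate
setClass("VelocityEstimate",
  representation(velocity = "numeric", method = "character",
                 nObservations = "integer", dispersion = "numeric",
                 roi = "character"),
  validity = function(object) {
    if (object@nObservations < 1) return("nObservations must be >= 1")
    if (!is.na(object@dispersion) && object@dispersion < 0)
      return("dispersion must be >= 0")
    TRUE
  })

#' DiameterEstimate: per-vessel diameter from FWHM profiles
#'
#' @slot diameter mean of the per-line widths, micrometres.
#' @slot perLineWidths micrometres, one per usable cross-line.
#' @slot nLines number of usable lines.
#' @slot nDropped lines excluded (out of bounds or no measurable width).
#' @slot method "crossline" or "manual".
#' @slot roi vessel identifier.
#' @aliases DiameterEstimate
#' @exportClass DiameterEstimate
setClass("DiameterEstimate",
  representation(diameter = "numeric", perLineWidths = "numeric",
                 nLines = "integer", nDropped = "integer",
                 method = "character", roi = "character"),
  validity = function(object) {
    if (any(object@perLineWidths <= 0)) return("widths must be positive")
    if (abs(object@diameter - mean(object@perLineWidths)) > 1e-8)
      return("diameter must equal the mean of perLineWidths")
    TRUE
  })

#' ShearRateEstimate: Poiseuille wall shear approximation
#'
#' @slot shearRate per second, `8 * |velocity| / diameter`.
#' @slot velocity signed micrometres per second as supplied.
#' @slot diameter micrometres.
#' @slot roi vessel identifier.
#' @aliases ShearRateEstimate
#' @exportClass ShearRateEstimate
setClass("ShearRateEstimate",
  representation(shearRate = "numeric", velocity = "numeric",
                 diameter = "numeric", roi = "character"))

#' LeakageMeasurement: Evans-blue extravasation ratio
#'
#' @slot ratio extravascular mean / intravascular mean (dimensionless).
#' @slot intravascularMean mean intensity over the vessel-centre FOV.
#' @slot extravascularMean mean intensity over the adjacent FOV.
#' @slot vesselFov,adjacentFov pixel rectangles (y0, x0, height, width).
#' @slot framesAveraged frames averaged to form the input image.
#' @aliases LeakageMeasurement
#' @exportClass LeakageMeasurement
setClass("LeakageMeasurement",
  representation(ratio = "numeric", intravascularMean = "numeric",
                 extravascularMean = "numeric", vesselFov = "numeric",
                 adjacentFov = "numeric", framesAveraged = "integer"))

#' OrganMask / ShellMask: cleared-organ segmentation products
#'
#' `OrganMask` is a boolean volume marking organ voxels; `ShellMask` is its
#' peripheral shell within a fixed distance of the organ edge.
#'
#' @slot mask logical array `[y, x, z]`.
#' @slot voxelSize micrometres per voxel (y, x, z).
#' @slot provenance one of "threshold", "manual", "truth".
#' @aliases OrganMask
#' @exportClass OrganMask
setClass("OrganMask",
  representation(mask = "array", voxelSize = "numeric",
                 provenance = "character"),
  validity = function(object) {
    if (!any(object@mask)) return("organ mask is empty")
    TRUE
  })

#' @slot depth shell depth in micrometres (distance to the organ edge).
#' @describeIn OrganMask-class peripheral shell of the organ mask.
#' @aliases ShellMask
#' @exportClass ShellMask
setClass("ShellMask",
  representation(mask = "array", voxelSize = "numeric", depth = "numeric"))

#' GroupComparison: two-group test result
#'
#' @slot metricName measured quantity.
#' @slot labels group labels (reference first).
#' @slot nA,nB group sizes.
#' @slot means,sds per-group mean and SD (reference first).
#' @slot testUsed "t_test" or "mann_whitney".
#' @slot statistic test statistic (t or U).
#' @slot pValue two-sided p-value.
#' @slot percentDifference `100 * (meanA - meanB) / meanA` (positive =
#'   reduction relative to the reference group).
#' @slot normalityP Shapiro-Wilk p-values used for the test choice.
#' @slot exact TRUE if the Mann-Whitney p came from full enumeration.
#' @aliases GroupComparison
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(metricName = "character", labels = "character",
                 nA = "integer", nB = "integer", means = "numeric",
                 sds = "numeric", testUsed = "character",
                 statistic = "numeric", pValue = "numeric",
                 percentDifference = "numeric", normalityP = "numeric",
                 exact = "logical"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1)
      return("pValue must lie in [0, 1]")
    TRUE
  })

#' GridAreaEstimate: organ footprint on a gridded reference
#'
#' @slot percentArea percent of grid cells covered (fractional coverage).
#' @slot gridCellSize micrometres per cell side.
#' @slot cellsTotal number of grid cells over the frame.
#' @slot cellsCovered sum of per-cell covered fractions.
#' @aliases GridAreaEstimate
#' @exportClass GridAreaEstimate
setClass("GridAreaEstimate",
  representation(percentArea = "numeric", gridCellSize = "numeric",
                 cellsTotal = "numeric", cellsCovered = "numeric"))

# ---- accessors ----

#' Accessors for ThymoVasc containers
#'
#' Small generic accessors for the S4 containers; prefer these over direct
#' slot access.
#'
#' @param x an object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "FlowMovie", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "FlowMovie", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "Kymograph", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "FlowMovie", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "Kymograph", function(x) x@frameRate)

#' @rdname accessors
#' @export
nFrames <- function(x) dim(x@frames)[3]

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "VolumeStack", function(x) x@voxels)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "VolumeStack", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "OrganMask", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "ShellMask", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("axisCoords", function(x) standardGeneric("axisCoords"))
#' @rdname accessors
#' @export
setMethod("axisCoords", "VesselAxis", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "OrganMask", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("maskArray", "ShellMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))
#' @rdname accessors
#' @export
setMethod("velocity", "VelocityEstimate", function(x) x@velocity)
#' @rdname accessors
#' @export
setMethod("velocity", "ShearRateEstimate", function(x) x@velocity)

#' @rdname accessors
#' @export
setGeneric("diameter", function(x) standardGeneric("diameter"))
#' @rdname accessors
#' @export
setMethod("diameter", "DiameterEstimate", function(x) x@diameter)
#' @rdname accessors
#' @export
setMethod("diameter", "ShearRateEstimate", function(x) x@diameter)

#' @rdname accessors
#' @export
shearValue <- function(x) x@shearRate

#' @rdname accessors
#' @export
leakRatio <- function(x) x@ratio

#' @rdname accessors
#' @export
pValue <- function(x) x@pValue

# ---- show methods ----

setMethod("show", "FlowMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FlowMovie: %d x %d px, %d frames | %.3g um/px @ %g fps [%s]\n",
              d[1], d[2], d[3], object@pixelSize, object@frameRate,
              object@channel))
})

setMethod("show", "VolumeStack", function(object) {
  d <- dim(object@voxels)
  v <- object@voxelSize
  cat(sprintf("VolumeStack: %d x %d x %d voxels | %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], v["y"], v["x"], v["z"]))
})

setMethod("show", "VelocityEstimate", function(object) {
  cat(sprintf("VelocityEstimate [%s/%s]: %.2f um/s (SD %.2f, n = %d)\n",
              object@roi, object@method, object@velocity,
              object@dispersion, object@nObservations))
})

setMethod("show", "DiameterEstimate", function(object) {
  cat(sprintf("DiameterEstimate [%s/%s]: %.2f um (n = %d lines, %d dropped)\n",
              object@roi, object@method, object@diameter, object@nLines,
              object@nDropped))
})

setMethod("show", "ShearRateEstimate", function(object) {
  cat(sprintf("ShearRateEstimate [%s]: %.1f 1/s (v = %.1f um/s, d = %.2f um)\n",
              object@roi, object@shearRate, object@velocity,
              object@diameter))
})

setMethod("show", "LeakageMeasurement", function(object) {
  cat(sprintf(
    "LeakageMeasurement: ratio %.4f (extravascular %.2f / intravascular %.2f, %d frames averaged)\n",
    object@ratio, object@extravascularMean, object@intravascularMean,
    object@framesAveraged))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison [%s]: %s (n=%d, mean %.4g) vs %s (n=%d, mean %.4g)\n  %s: p = %.4g, %% difference = %.3g\n",
    object@metricName, object@labels[1], object@nA, object@means[1],
    object@labels[2], object@nB, object@means[2], object@testUsed,
    object@pValue, object@percentDifference))
})
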