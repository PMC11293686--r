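# File interchange.
#
# Movies and volumes travel as multi-page 32-bit float TIFF (one page per
# frame or slice) with a JSON sidecar (`<path>.json`) carrying the
# physical calibration and an affine intensity code: TIFF pages store
# (intensity - intensityOffset) / intensityScale in [0, 1] (the float
# TIFF writer only accepts that range). Masks are 8-bit TIFF (0/255).
# ROIs (vessel axes, manual lines) are JSON; alignment shifts and
# measurement records are CSV.

#' Write / read a FlowMovie as multi-page float TIFF
#'
#' @param movie a [FlowMovie-class].
#' @param path TIFF path; a `<path>.json` sidecar stores pixel size,
#'   frame rate, channel and intensity scale.
#' @return `writeMovieTiff` returns `path` invisibly; `readMovieTiff`
#'   returns a [FlowMovie-class].
#' @export
writeMovieTiff <- function(movie, path) {
  fr <- frames(movie)
  off <- min(fr)
  sc <- max(max(fr) - off, 1e-12)
  pages <- lapply(seq_len(dim(fr)[3]), function(t) (fr[, , t] - off) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = "FlowMovie", pixelSizeUm = pixelSize(movie),
               frameRate = frameRate(movie), channel = movie@channel,
               intensityScale = sc, intensityOffset = off)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages))
    arr[, , t] <- pages[[t]] * meta$intensityScale + meta$intensityOffset
  FlowMovie(arr, pixelSize = meta$pixelSizeUm, frameRate = meta$frameRate,
            channel = meta$channel)
}

#' Write / read a VolumeStack as multi-page float TIFF
#'
#' @param volume a [VolumeStack-class].
#' @param path TIFF path; the `<path>.json` sidecar stores the voxel size
#'   and intensity scale.
#' @return `writeVolumeTiff` returns `path` invisibly; `readVolumeTiff`
#'   returns a [VolumeStack-class].
#' @export
writeVolumeTiff <- function(volume, path) {
  v <- voxels(volume)
  off <- min(v)
  sc <- max(max(v) - off, 1e-12)
  pages <- lapply(seq_len(dim(v)[3]), function(k) (v[, , k] - off) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = "VolumeStack",
               voxelSizeUm = as.list(voxelSize(volume)),
               intensityScale = sc, intensityOffset = off)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVolumeTiff
#' @export
readVolumeTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages))
    arr[, , k] <- pages[[k]] * meta$intensityScale + meta$intensityOffset
  VolumeStack(arr, voxelSize = unlist(meta$voxelSizeUm))
}

#' Write a boolean mask (2D or 3D) as 8-bit TIFF
#'
#' @param mask logical matrix or array `[y, x, z]`.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
writeMaskTiff <- function(mask, path) {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1))
  pages <- lapply(seq_len(dim(mask)[3]), function(k) (mask[, , k]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write / read vessel axis ROIs as JSON
#'
#' Each axis is stored as a list of (y, x) pixel coordinates with its id;
#' the file records the pixel size the coordinates refer to.
#'
#' @param axes list of [VesselAxis-class].
#' @param path JSON path.
#' @param pixelSize micrometres per pixel of the coordinate frame.
#' @return `writeAxisJson` returns `path` invisibly; `readAxisJson`
#'   returns a named list of [VesselAxis-class] with a `pixelSize`
#'   attribute.
#' @export
writeAxisJson <- function(axes, path, pixelSize = 0.31) {
  payload <- list(
    pixelSizeUm = pixelSize,
    axes = lapply(axes, function(a)
      list(id = a@id, points = unname(apply(axisCoords(a), 1, as.list)),
           zSlice = attr(a, "zSlice"))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeAxisJson
#' @export
readAxisJson <- function(path) {
  payload <- jsonlite::read_json(path)
  axes <- lapply(payload$axes, function(a) {
    co <- do.call(rbind, lapply(a$points, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    ax <- VesselAxis(co, id = a$id)
    if (!is.null(a$zSlice)) attr(ax, "zSlice") <- as.numeric(a$zSlice)
    ax
  })
  names(axes) <- vapply(axes, function(a) a@id, character(1))
  attr(axes, "pixelSize") <- as.numeric(payload$pixelSizeUm)
  axes
}

#' Export alignment shifts as CSV
#'
#' One row per frame: frame, dy_px, dx_px, low_confidence.
#'
#' @param alignment an [AlignmentResult-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
exportShiftsCsv <- function(alignment, path) {
  df <- data.frame(frame = seq_len(nrow(alignment@shifts)),
                   dy_px = alignment@shifts[, 1],
                   dx_px = alignment@shifts[, 2],
                   low_confidence = alignment@lowConfidence)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a measurement record row
#'
#' The long-format schema shared by the statistics layer: animal_id,
#' group, metric, value, units, method, roi_id, seed, timestamp.
#'
#' @param animalId,group,metric,value,units,method,roiId,seed record
#'   fields; `seed` may be NA for manual measurements.
#' @return One-row data.frame.
#' @export
measurementRecord <- function(animalId, group, metric, value, units,
                              method = NA_character_,
                              roiId = NA_character_, seed = NA_integer_) {
  data.frame(animal_id = animalId, group = group, metric = metric,
             value = value, units = units, method = method,
             roi_id = roiId, seed = seed,
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Export measurement records as CSV
#'
#' @param records data.frame of rows from [measurementRecord()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
exportMeasurementsCsv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write a kymograph as a single-page float TIFF
#'
#' Rows are frames, columns arc-length positions; the sidecar records the
#' calibration and intensity code as for movies.
#'
#' @param kymo a [Kymograph-class].
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
writeKymographTiff <- function(kymo, path) {
  k <- kymo@data
  off <- min(k)
  sc <- max(max(k) - off, 1e-12)
  tiff::writeTIFF((k - off) / sc, path, bits.per.sample = 32L)
  meta <- list(kind = "Kymograph", pixelSizeUm = kymo@pixelSize,
               frameRate = kymo@frameRate, axisId = kymo@axisId,
               intensityScale = sc, intensityOffset = off)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export per-line FWHM widths as CSV
#'
#' One row per usable cross-line: vessel_id, line_index, width_um.
#'
#' @param estimate a [DiameterEstimate-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
exportWidthsCsv <- function(estimate, path) {
  df <- data.frame(vessel_id = estimate@roi,
                   line_index = seq_along(estimate@perLineWidths),
                   width_um = estimate@perLineWidths)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
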