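# Frame alignment and preprocessing.
#
# Time-lapse frames are aligned by translation-only subpixel phase
# correlation against a reference frame; the testable contract is recovery
# of known rigid shifts, not any particular feature detector. Cleared
# volumes get the standard chain: halve y/x (2x2 block mean per slice),
# 3x3 median per slice, then 2D Gaussian blur (sigma = 2 px) per slice.

# Cross-correlation shift of `img` relative to `ref`:
# img(y, x) ~ ref(y - dy, x - dx). Returns c(dy, dx, peak) where peak is
# the normalised correlation maximum. FFT cross-correlation of
# mean-subtracted, Hann-windowed frames is used rather than whitened phase
# correlation: the scenes are smooth (vessel walls, cell blobs), so
# whitening would amplify empty high frequencies.
phaseCorrShift <- function(ref, img, eps = 1e-12) {
  nr <- nrow(ref); nc <- ncol(ref)
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  w <- outer(wy, wx)
  a <- (ref - mean(ref)) * w
  b <- (img - mean(img)) * w
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Fb * Conj(Fa)
  corr <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  corr <- corr / max(sqrt(sum(a^2) * sum(b^2)), eps)
  pk <- which.max(corr)
  py <- (pk - 1) %% nr + 1
  px <- (pk - 1) %/% nr + 1
  wrap <- function(i, n) if (i - 1 > n / 2) i - 1 - n else i - 1
  d <- c(wrap(py, nr), wrap(px, nc))
  peak <- corr[py, px]
  # gradient-based (optical-flow) subpixel refinement: undo the integer
  # shift, then solve the linearised residual shift; repeat. Both frames
  # are lightly smoothed first (smoothing commutes with translation, so
  # the estimate stays unbiased while noise-induced gradient bias drops).
  refS <- gblur2d(ref, 1)
  imgS <- gblur2d(img, 1)
  ref <- refS
  for (iter in 1:3) {
    bb <- translateImage(imgS, -d[1], -d[2])
    m <- ceiling(max(abs(d))) + 2
    ys <- (m + 1):(nr - m); xs <- (m + 1):(nc - m)
    if (length(ys) < 5 || length(xs) < 5) break
    gy <- (ref[ys + 1, xs] - ref[ys - 1, xs]) / 2
    gx <- (ref[ys, xs + 1] - ref[ys, xs - 1]) / 2
    dd <- bb[ys, xs] - ref[ys, xs]
    A <- matrix(c(sum(gy * gy), sum(gy * gx), sum(gy * gx),
                  sum(gx * gx)), 2, 2)
    if (abs(det(A)) < eps) break
    rho <- -solve(A, c(sum(gy * dd), sum(gx * dd)))
    d <- d + rho
    if (max(abs(rho)) < 0.01) break
  }
  c(dy = d[1], dx = d[2], peak = peak)
}

#' Align movie frames by rigid translation
#'
#' Estimates the per-frame translation relative to a reference frame by
#' subpixel phase correlation and removes it (linear interpolation, edge
#' values replicated). Featureless (constant) frames get shift (0, 0) and
#' are flagged low-confidence rather than raising an error.
#'
#' @param movie a [FlowMovie-class] with at least 2 frames.
#' @param referenceIndex frame to align to (default 1).
#' @param peakThreshold phase-correlation peak below which a frame is
#'   flagged low-confidence.
#' @return An [AlignmentResult-class]: aligned movie, `n x 2` shift matrix
#'   (dy, dx) with the reference row (0, 0), and per-frame confidence
#'   flags.
#' @export
alignFrames <- function(movie, referenceIndex = 1L, peakThreshold = 0.01) {
  fr <- frames(movie)
  n <- dim(fr)[3]
  if (n < 2) stop("movie must have at least 2 frames")
  referenceIndex <- as.integer(referenceIndex)
  if (referenceIndex < 1 || referenceIndex > n)
    stop("referenceIndex out of range")
  ref <- fr[, , referenceIndex]
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  low <- logical(n)
  refFlat <- stats::sd(ref) < .Machine$double.eps^0.5
  out <- fr
  for (t in seq_len(n)) {
    if (t == referenceIndex) next
    img <- fr[, , t]
    if (refFlat || stats::sd(img) < .Machine$double.eps^0.5) {
      low[t] <- TRUE
      next
    }
    est <- phaseCorrShift(ref, img)
    shifts[t, ] <- est[c("dy", "dx")]
    low[t] <- est["peak"] < peakThreshold
    out[, , t] <- translateImage(img, -est["dy"], -est["dx"])
  }
  new("AlignmentResult",
      alignedMovie = FlowMovie(out, pixelSize = pixelSize(movie),
                               frameRate = frameRate(movie),
                               channel = movie@channel),
      shifts = shifts, referenceIndex = referenceIndex,
      lowConfidence = low)
}

#' Average consecutive movie frames
#'
#' Pixel-wise arithmetic mean of `n` frames starting at `start`; leakage
#' measurements use a 30-frame average by convention.
#'
#' @param movie a [FlowMovie-class].
#' @param start first frame (default 1).
#' @param n number of frames to average (default 30).
#' @return Numeric matrix (the averaged image).
#' @export
averageFrames <- function(movie, start = 1L, n = 30L) {
  fr <- frames(movie)
  if (n < 1) stop("n must be >= 1")
  if (start < 1 || start + n - 1 > dim(fr)[3])
    stop("frame range out of bounds")
  sub <- fr[, , start:(start + n - 1), drop = FALSE]
  matrix(rowMeans(matrix(sub, prod(dim(fr)[1:2]), n)), dim(fr)[1],
         dim(fr)[2])
}

#' Preprocess a cleared-organ volume
#'
#' Applies, in order: 2x downscale in y and x (2x2 block mean, per slice),
#' a 3x3 median (despeckle) per slice, and a 2D Gaussian blur of sigma = 2
#' px per slice. The y/x voxel size metadata is doubled. Filtering is 2D
#' per slice, matching the slice-wise workflow the chain models; constants
#' are preserved exactly.
#'
#' @param volume a [VolumeStack-class].
#' @param gaussSigma blur SD in pixels of the downscaled image (default 2).
#' @return A preprocessed [VolumeStack-class].
#' @export
preprocessVolume <- function(volume, gaussSigma = 2) {
  v <- voxels(volume)
  d <- dim(v)
  if (d[1] %/% 2 < 2 || d[2] %/% 2 < 2)
    stop("volume too small to downscale")
  nz <- d[3]
  out <- array(0, c(d[1] %/% 2, d[2] %/% 2, nz))
  for (k in seq_len(nz)) {
    sl <- blockDownscale2(v[, , k])
    sl <- median3x3(sl)
    out[, , k] <- gblur2d(sl, gaussSigma)
  }
  vs <- voxelSize(volume)
  VolumeStack(out, voxelSize = c(y = unname(vs["y"]) * 2,
                                 x = unname(vs["x"]) * 2,
                                 z = unname(vs["z"])))
}
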