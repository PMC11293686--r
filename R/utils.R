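# Internal numerics shared across modules.
#
# Image convention: a single frame/slice is a numeric matrix indexed
# [row = y, col = x], 1-based, so a point is written (y, x). Volumes are
# arrays [y, x, z]; movies [y, x, t]. Rectangles are (y0, x0, height,
# width) in pixels, covering rows y0 .. y0 + height - 1.

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Bilinear sampling with edge clamping; y, x may be fractional vectors.
bilinearSample <- function(img, y, x) {
  nr <- nrow(img); nc <- ncol(img)
  y <- pmin(pmax(y, 1), nr)
  x <- pmin(pmax(x, 1), nc)
  y0 <- pmin(floor(y), nr - 1L); x0 <- pmin(floor(x), nc - 1L)
  if (nr == 1L) y0 <- rep(1, length(y))
  if (nc == 1L) x0 <- rep(1, length(x))
  fy <- y - y0; fx <- x - x0
  y1 <- pmin(y0 + 1L, nr); x1 <- pmin(x0 + 1L, nc)
  i00 <- img[cbind(y0, x0)]; i01 <- img[cbind(y0, x1)]
  i10 <- img[cbind(y1, x0)]; i11 <- img[cbind(y1, x1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Translate image content by (dy, dx): out(y, x) = img(y - dy, x - dx),
# bilinear interpolation, edge values replicated outside the frame.
translateImage <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  yy <- matrix(seq_len(nr), nr, nc) - dy
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc) - dx
  matrix(bilinearSample(img, as.vector(yy), as.vector(xx)), nr, nc)
}

# Exact 3x3 median filter (replicate padding) via Paeth's median-of-9
# exchange network, vectorised over all pixels.
median3x3 <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mat
  pad[1, ] <- pad[2, ]; pad[nr + 2, ] <- pad[nr + 1, ]
  pad[, 1] <- pad[, 2]; pad[, nc + 2] <- pad[, nc + 1]
  p <- vector("list", 9)
  k <- 0
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1
    p[[k]] <- as.vector(pad[dy + seq_len(nr), dx + seq_len(nc)])
  }
  sw <- function(a, b) {
    lo <- pmin(p[[a]], p[[b]]); hi <- pmax(p[[a]], p[[b]])
    p[[a]] <<- lo; p[[b]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  matrix(p[[5]], nr, nc)
}

# 2x2 block-mean downscale of a matrix (trailing odd row/col dropped).
blockDownscale2 <- function(mat) {
  nr <- 2L * (nrow(mat) %/% 2L); nc <- 2L * (ncol(mat) %/% 2L)
  m <- mat[seq_len(nr), seq_len(nc), drop = FALSE]
  (m[seq(1, nr, 2), seq(1, nc, 2), drop = FALSE] +
   m[seq(2, nr, 2), seq(1, nc, 2), drop = FALSE] +
   m[seq(1, nr, 2), seq(2, nc, 2), drop = FALSE] +
   m[seq(2, nr, 2), seq(2, nc, 2), drop = FALSE]) / 4
}

# Union-find over integer labels 1..n.
ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# 8-connected labelling of a 2D logical mask. EBImage::bwlabel is
# 4-connected; merge labels that touch diagonally.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  mx <- max(lab)
  if (mx <= 1) return(lab)
  parent <- seq_len(mx)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- ufFind(parent, pairs[r, 1]); b <- ufFind(parent, pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(mx), function(i) ufFind(parent, i), integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# 3D connected components (26-connectivity in effect): per-slice
# 8-connected labels merged across consecutive slices wherever labelled
# voxels share or touch an (y, x) footprint.
label3d <- function(vol) {
  nz <- dim(vol)[3]
  labs <- vector("list", nz)
  offset <- 0L
  for (k in seq_len(nz)) {
    l <- label8(vol[, , k])
    mx <- max(0L, max(l))
    l[l > 0] <- l[l > 0] + offset
    offset <- offset + mx
    labs[[k]] <- l
  }
  if (offset == 0L) return(array(0L, dim(vol)))
  parent <- seq_len(offset)
  unite <- function(a, b) {
    ra <- ufFind(parent, a); rb <- ufFind(parent, b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- dim(vol)[1]; nc <- dim(vol)[2]
  for (k in seq_len(nz - 1L)) {
    a <- labs[[k]]; b <- labs[[k + 1L]]
    shifts <- list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    for (s in shifts) {
      ys <- seq_len(nr); xs <- seq_len(nc)
      ya <- ys[ys + s[1] >= 1 & ys + s[1] <= nr]
      xa <- xs[xs + s[2] >= 1 & xs + s[2] <= nc]
      pa <- a[ya, xa, drop = FALSE]
      pb <- b[ya + s[1], xa + s[2], drop = FALSE]
      hit <- pa > 0 & pb > 0
      if (any(hit)) {
        pr <- unique(cbind(pa[hit], pb[hit]))
        for (r in seq_len(nrow(pr))) unite(pr[r, 1], pr[r, 2])
      }
    }
  }
  root <- vapply(seq_len(offset), function(i) ufFind(parent, i), integer(1))
  relab <- match(root, sort(unique(root)))
  out <- array(0L, dim(vol))
  for (k in seq_len(nz)) {
    l <- labs[[k]]
    l[l > 0] <- relab[l[l > 0]]
    out[, , k] <- l
  }
  out
}

# Cumulative arc length of an n x 2 polyline (y, x).
polyArcLength <- function(coords) {
  if (nrow(coords) < 2) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

# Resample a polyline at arc-length positions `s` (vector, in px from the
# first vertex). Returns list(points = n x 2, tangents = n x 2 unit).
polylineAt <- function(coords, s) {
  seg <- diff(coords)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  seg <- seg[keep, , drop = FALSE]; len <- len[keep]
  starts <- coords[c(TRUE, keep), , drop = FALSE]
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(len))
  frac <- (s - cum[idx]) / len[idx]
  pts <- starts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tans <- seg[idx, , drop = FALSE] / len[idx]
  list(points = pts, tangents = tans, total = total)
}

# Minimum distance from each point (rows of `pts`, (y, x)) to a polyline.
# Also returns the arc-length position of the closest point.
distanceToPolyline <- function(pts, coords) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  bestS <- rep(0, n)
  seg <- diff(coords)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  for (i in seq_len(nrow(seg))) {
    if (len[i] == 0) next
    a <- coords[i, ]
    d <- seg[i, ]
    t <- ((pts[, 1] - a[1]) * d[1] + (pts[, 2] - a[2]) * d[2]) / (len[i]^2)
    t <- pmin(pmax(t, 0), 1)
    dy <- pts[, 1] - (a[1] + t * d[1])
    dx <- pts[, 2] - (a[2] + t * d[2])
    di <- sqrt(dy * dy + dx * dx)
    upd <- di < best
    best[upd] <- di[upd]
    bestS[upd] <- cum[i] + t[upd] * len[i]
  }
  list(distance = best, arc = bestS)
}

# Even-odd rasterisation of a polygon (n x 2, (y, x) px vertices) onto an
# nr x nc logical matrix; pixel centres at integer coordinates.
rasterizePolygon <- function(poly, nr, nc) {
  ys <- matrix(seq_len(nr), nr, nc)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  px <- as.vector(xs); py <- as.vector(ys)
  inside <- rep(FALSE, length(px))
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, nr, nc)
}

# Gaussian blur of one 2D slice, replicate boundary.
gblur2d <- function(mat, sigma) {
  img <- EBImage::gblur(EBImage::Image(mat), sigma = sigma,
                        boundary = "replicate")
  EBImage::imageData(img)
}
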