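# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_thighseg <- function(...) stop(..., call. = FALSE)

# Bilinear interpolation of img (matrix [row, col]) at 0-based coordinates
# (x = col, y = row). Coordinates are clamped to the image rectangle, which
# gives edge replication outside the grid.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(x0, nc - 2); y0 <- pmin(y0, nr - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * nr + y0 + 1
  v00 <- img[i00]; v10 <- img[i00 + nr]
  v01 <- img[i00 + 1]; v11 <- img[i00 + nr + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# Separable Gaussian smoothing with reflective padding (zero-flux borders).
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  off <- -rad:rad
  kern <- exp(-off^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 2L - i, i)
    i <- ifelse(i > n, 2L * n - i, i)
    pmin(pmax(i, 1L), n)
  }
  nr <- nrow(img); nc <- ncol(img)
  tmp <- matrix(0, nr, nc)
  for (j in seq_along(off)) {
    tmp <- tmp + kern[j] * img[reflect(seq_len(nr) + off[j], nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(off)) {
    out <- out + kern[j] * tmp[, reflect(seq_len(nc) + off[j], nc), drop = FALSE]
  }
  out
}

# Central-difference gradients of a matrix, replicated edges (zero-flux).
# Returns list(gx, gy) where gx is the derivative along columns (x) and gy
# along rows (y).
central_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  cl <- c(1L, seq_len(nc - 1L)); cr <- c(seq_len(nc)[-1L], nc)
  rt <- c(1L, seq_len(nr - 1L)); rb <- c(seq_len(nr)[-1L], nr)
  gx <- (img[, cr, drop = FALSE] - img[, cl, drop = FALSE]) / 2
  gy <- (img[rb, , drop = FALSE] - img[rt, , drop = FALSE]) / 2
  list(gx = gx, gy = gy)
}

# Shoelace polygon area (absolute), points as n x 2 matrix (x, y).
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_centroid <- function(pts) {
  colMeans(pts)
}

# Points of a closed polygon resampled to n points at uniform arc length,
# starting at the first input vertex.
resample_closed <- function(pts, n) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(matrix(rep(pts[1, ], each = n), n, 2))
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(closed) - 1L)
  frac <- (target - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE])
}

# all-points-inside test used by phantom nesting checks (even-odd, tolerant)
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  for (i in seq_len(n)) {
    crosses <- (ys[i] <= py & py < ye[i]) | (ye[i] <= py & py < ys[i])
    if (!any(crosses)) next
    xint <- xs[i] + (py - ys[i]) * (xe[i] - xs[i]) / (ye[i] - ys[i])
    inside <- xor(inside, crosses & xint > px)
  }
  inside
}
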