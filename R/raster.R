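# Raster geometry: polygon filling under the pixel-center rule, convex hull
# rasterization, connected components, mask boundaries.

#' Rasterize a closed polygon with the pixel-center rule
#'
#' A pixel belongs to the polygon iff its center (at integer 0-based
#' `(col, row)` coordinates) is inside under the even-odd rule; boundary ties
#' are broken toward lower row/col (left/top edges included, right/bottom
#' excluded), so an axis-aligned w x h rectangle with corners at pixel
#' centers covers exactly w*h pixels.
#'
#' @param poly n x 2 matrix of `(x = col, y = row)` vertices, 0-based.
#' @param nr,nc Grid size (rows, cols).
#' @return Integer matrix `nr x nc` with values 0/1.
#' @export
fill_polygon <- function(poly, nr, nc) {
  mask <- matrix(0L, nr, nc)
  if (is.null(poly) || nrow(poly) < 3) return(mask)
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  keep <- ys != ye  # horizontal edges never span a scanline
  if (!any(keep)) return(mask)
  xs <- xs[keep]; ys <- ys[keep]; xe <- xe[keep]; ye <- ye[keep]
  r0 <- max(0L, floor(min(ys, ye))); r1 <- min(nr - 1L, ceiling(max(ys, ye)))
  if (r1 < r0) return(mask)
  for (y in r0:r1) {
    span <- (ys <= y & y < ye) | (ye <= y & y < ys)
    if (!any(span)) next
    xint <- xs[span] + (y - ys[span]) * (xe[span] - xs[span]) / (ye[span] - ys[span])
    xint <- sort(xint)
    # pixel x inside iff #{xint <= x} is odd
    cols <- 0:(nc - 1L)
    cnt <- findInterval(cols, xint)
    inside <- cols[cnt %% 2L == 1L]
    if (length(inside)) mask[y + 1L, inside + 1L] <- 1L
  }
  mask
}

# re-rasterization of evolved contours (same pixel-center rule as any other
# closed outline)
contour_to_mask <- function(poly, nr, nc) {
  fill_polygon(poly, nr, nc)
}

#' Rasterized convex hull of a binary mask
#'
#' Convex hull of the foreground pixel centers, rasterized inclusively: a
#' pixel belongs to the hull iff its center is inside or on the hull
#' boundary. For a convex mask this reproduces the mask itself.
#'
#' @param mask Binary matrix (0/1).
#' @return Integer 0/1 matrix of the same size.
#' @export
convex_hull_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask != 0)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(out)
  py <- (idx - 1L) %% nr          # 0-based row
  px <- (idx - 1L) %/% nr         # 0-based col
  if (length(idx) <= 2) { out[idx] <- 1L; return(out) }
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  m <- length(h)
  if (m < 3) { out[idx] <- 1L; return(out) }
  ex <- hx[c(2:m, 1)] - hx; ey <- hy[c(2:m, 1)] - hy
  # orientation from the signed area so the interior half-plane sign is known
  orient <- sign(sum(hx * hy[c(2:m, 1)] - hx[c(2:m, 1)] * hy))
  if (orient == 0) { out[idx] <- 1L; return(out) }
  c0 <- max(0L, min(hx)); c1 <- min(nc - 1L, max(hx))
  r0 <- max(0L, min(hy)); r1 <- min(nr - 1L, max(hy))
  gx <- rep(c0:c1, each = r1 - r0 + 1L)
  gy <- rep(r0:r1, times = c1 - c0 + 1L)
  inside <- rep(TRUE, length(gx))
  for (i in seq_len(m)) {
    cr <- orient * (ex[i] * (gy - hy[i]) - ey[i] * (gx - hx[i]))
    inside <- inside & cr >= -1e-9
  }
  out[cbind(gy[inside] + 1L, gx[inside] + 1L)] <- 1L
  out
}

#' 8-connected component labeling
#'
#' @param mask Binary matrix; non-zero pixels are foreground.
#' @return Integer matrix of component labels (0 = background), labels in
#'   scan order.
#' @export
label_components <- function(mask) {
  storage.mode(mask) <- "integer"
  label_components_cpp(mask)
}

# largest 8-connected component of a mask (empty mask returned as-is)
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) <= 1L) return((mask != 0) + 0L)
  sizes <- tabulate(lab[lab > 0L])
  (lab == which.max(sizes)) + 0L
}

# ordered boundary contour (0-based (col,row)) of the largest component of a
# binary mask; NULL when empty
mask_boundary <- function(mask) {
  m <- largest_component(mask)
  if (sum(m) == 0) return(NULL)
  oc <- EBImage::ocontour(t(m))
  pts <- oc[[which.max(vapply(oc, nrow, 1L))]]
  matrix(as.numeric(pts), ncol = 2)
}
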