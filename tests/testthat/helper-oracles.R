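# Independent brute-force oracles used to freeze expected values.

# lower median of a k x k neighborhood with reflective padding, enumerated
# pixel by pixel
oracle_median_filter <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  lo <- if (k %% 2 == 0) -(k / 2 - 1) else -(k - 1) / 2
  hi <- k %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- img
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- c()
    for (dr in lo:hi) for (dc in lo:hi)
      vals <- c(vals, img[refl(r + dr, nr), refl(c + dc, nc)])
    out[r, c] <- sort(vals)[ceiling(length(vals) / 2)]
  }
  out
}

# pixel-center point-in-polygon by even-odd ray casting with the
# lower-row/col tie rule, evaluated center by center
oracle_fill_polygon <- function(poly, nr, nc) {
  mask <- matrix(0L, nr, nc)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  for (y in 0:(nr - 1)) for (x in 0:(nc - 1)) {
    cross <- 0L
    for (i in seq_len(n)) {
      if (ys[i] == ye[i]) next
      if ((ys[i] <= y && y < ye[i]) || (ye[i] <= y && y < ys[i])) {
        xint <- xs[i] + (y - ys[i]) * (xe[i] - xs[i]) / (ye[i] - ys[i])
        if (xint <= x) cross <- cross + 1L
      }
    }
    if (cross %% 2L == 1L) mask[y + 1, x + 1] <- 1L
  }
  mask
}

# exhaustive flood fill (8-connectivity) via repeated neighbor expansion
oracle_label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (mask[r, c] == 0 || lab[r, c] != 0) next
    nxt <- nxt + 1L
    frontier <- matrix(c(r, c), 1)
    lab[r, c] <- nxt
    while (nrow(frontier) > 0) {
      nxt_frontier <- NULL
      for (i in seq_len(nrow(frontier))) {
        for (dr in -1:1) for (dc in -1:1) {
          rr <- frontier[i, 1] + dr; cc <- frontier[i, 2] + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (mask[rr, cc] != 0 && lab[rr, cc] == 0) {
            lab[rr, cc] <- nxt
            nxt_frontier <- rbind(nxt_frontier, c(rr, cc))
          }
        }
      }
      frontier <- if (is.null(nxt_frontier)) matrix(0, 0, 2) else nxt_frontier
    }
  }
  lab
}

# convex-hull membership: a convex hull is the intersection of the closed
# half-planes of its supporting lines, and every supporting line through an
# edge passes through two of the points; enumerate all point pairs, keep the
# lines with the whole set on one closed side, and test query points against
# them
oracle_hull_membership <- function(px, py, qx, qy) {
  n <- length(px)
  inside <- rep(TRUE, length(qx))
  tol <- 1e-9
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ex <- px[j] - px[i]; ey <- py[j] - py[i]
    if (ex == 0 && ey == 0) next
    cr <- ex * (py - py[i]) - ey * (px - px[i])
    if (all(cr >= -tol)) {
      crq <- ex * (qy - py[i]) - ey * (qx - px[i])
      inside <- inside & crq >= -tol
    }
  }
  inside
}
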