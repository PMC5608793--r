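# Multi-component shapes, pose transforms and generalized Procrustes
# alignment — the geometry layer beneath the point distribution model.

#' Multi-component shape
#'
#' Ordered landmark/intermediate points of all eight thigh components
#' concatenated into one shape vector, with a contiguous index range per
#' component. Points are 0-based `(col, row)` pixel coordinates; each
#' component is a closed outline (closure implied, first/last points
#' distinct).
#'
#' @param points P x 2 numeric matrix `(x = col, y = row)`.
#' @param component Character or factor of length P assigning each point to
#'   one of [SHAPE_COMPONENTS] (contiguous blocks).
#' @return Object of class `thigh_shape` with fields `points` and
#'   `component` (factor).
#' @export
thigh_shape <- function(points, component) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || !all(is.finite(points)))
    stop_thighseg("points must be a finite P x 2 matrix")
  component <- factor(as.character(component), levels = unique(as.character(component)))
  if (length(component) != nrow(points))
    stop_thighseg("component labels must match the number of points")
  r <- rle(as.character(component))
  if (any(duplicated(r$values)))
    stop_thighseg("component point ranges must be contiguous")
  if (any(r$lengths < 3))
    stop_thighseg("each component outline needs at least 3 points")
  structure(list(points = points, component = component), class = "thigh_shape")
}

#' @export
print.thigh_shape <- function(x, ...) {
  cat(sprintf("<thigh_shape: %d points, components: %s>\n", nrow(x$points),
              paste(levels(x$component), table(x$component)[levels(x$component)],
                    sep = ":", collapse = " ")))
  invisible(x)
}

shape_vector <- function(shape) c(shape$points[, 1], shape$points[, 2])

vector_to_points <- function(v) matrix(v, ncol = 2)

#' Similarity pose
#'
#' Translation, isotropic scale and rotation placing a model-frame shape in
#' image coordinates: `p' = s * R(theta) * p + (tx, ty)`.
#'
#' @param tx,ty Translation in pixels.
#' @param s Scale, > 0.
#' @param theta Rotation in radians, wrapped to `(-pi, pi]`.
#' @return Object of class `thigh_pose`.
#' @export
pose <- function(tx = 0, ty = 0, s = 1, theta = 0) {
  if (s <= 0) stop_thighseg("pose scale must be positive")
  theta <- ((theta + pi) %% (2 * pi)) - pi
  if (theta == -pi) theta <- pi
  structure(list(tx = tx, ty = ty, s = s, theta = theta), class = "thigh_pose")
}

#' Apply a pose to points
#' @param pts n x 2 matrix.
#' @param p A [pose()].
#' @return Transformed n x 2 matrix.
#' @export
apply_pose <- function(pts, p) {
  cs <- cos(p$theta); sn <- sin(p$theta)
  x <- pts[, 1]; y <- pts[, 2]
  cbind(p$s * (cs * x - sn * y) + p$tx,
        p$s * (sn * x + cs * y) + p$ty)
}

#' Invert a pose
#' @param p A [pose()].
#' @return The inverse [pose()].
#' @export
invert_pose <- function(p) {
  cs <- cos(-p$theta); sn <- sin(-p$theta)
  tx <- -(cs * p$tx - sn * p$ty) / p$s
  ty <- -(sn * p$tx + cs * p$ty) / p$s
  pose(tx, ty, 1 / p$s, -p$theta)
}

# least-squares similarity transform mapping src to dst (complex formulation)
fit_similarity <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  zs <- complex(real = src[, 1] - cs[1], imaginary = src[, 2] - cs[2])
  zd <- complex(real = dst[, 1] - cd[1], imaginary = dst[, 2] - cd[2])
  denom <- sum(Conj(zs) * zs)
  if (Mod(denom) < 1e-12) stop_thighseg("degenerate shape in similarity fit")
  a <- sum(Conj(zs) * zd) / denom
  s <- Mod(a); th <- Arg(a)
  rot <- apply_pose(matrix(cs, 1, 2), pose(0, 0, s, th))
  pose(cd[1] - rot[1, 1], cd[2] - rot[1, 2], s, th)
}

#' Generalized Procrustes alignment of a shape set
#'
#' Iterative alignment of every shape to the evolving mean by least-squares
#' similarity transforms. The mean is centered at the origin with unit
#' centroid size; iteration stops when the mean moves less than `tol` (RMS).
#'
#' @param shapes List of [thigh_shape] with identical point counts and
#'   component layout.
#' @param tol Convergence tolerance on the mean update, default `1e-7`.
#' @param max_iter Safety cap on iterations.
#' @return List with `aligned` (list of [thigh_shape] in the Procrustes
#'   frame), `mean_shape` ([thigh_shape]), `transforms` (list of [pose()]
#'   mapping each input into the frame).
#' @export
align_shapes <- function(shapes, tol = 1e-7, max_iter = 100) {
  if (length(shapes) < 2) stop_thighseg("need at least 2 shapes")
  P <- nrow(shapes[[1]]$points)
  comp <- shapes[[1]]$component
  for (s in shapes) {
    if (nrow(s$points) != P || !identical(as.character(s$component), as.character(comp)))
      stop_thighseg("shapes must share point count and component layout")
    if (max(apply(s$points, 2, stats::sd)) < 1e-12)
      stop_thighseg("degenerate shape (all points identical)")
  }
  normalize <- function(pts) {
    pts <- sweep(pts, 2, colMeans(pts))
    pts / sqrt(sum(pts^2))
  }
  mean_pts <- normalize(shapes[[1]]$points)
  aligned <- lapply(shapes, function(s) s$points)
  transforms <- vector("list", length(shapes))
  for (it in seq_len(max_iter)) {
    for (i in seq_along(shapes)) {
      transforms[[i]] <- fit_similarity(shapes[[i]]$points, mean_pts)
      aligned[[i]] <- apply_pose(shapes[[i]]$points, transforms[[i]])
    }
    new_mean <- normalize(Reduce(`+`, aligned) / length(aligned))
    delta <- sqrt(mean((new_mean - mean_pts)^2))
    mean_pts <- new_mean
    if (delta < tol) break
  }
  list(
    aligned = lapply(aligned, thigh_shape, component = comp),
    mean_shape = thigh_shape(mean_pts, comp),
    transforms = transforms
  )
}

#' Train a point distribution model
#'
#' PCA of Procrustes-aligned shape vectors. The number of retained modes is
#' the smallest count whose eigenvalues reach `variance_retained` of the
#' total variance (capped at n - 1).
#'
#' @param aligned List of aligned [thigh_shape] (output of [align_shapes()]),
#'   at least 3.
#' @param variance_retained Fraction of variance to retain, in (0, 1].
#' @return Object of class `thigh_pdm`: `mean` (2P vector), `modes`
#'   (2P x m orthonormal), `eigenvalues` (length m, non-increasing),
#'   `variance_retained`, `component` (factor), `P`.
#' @export
train_pdm <- function(aligned, variance_retained = 0.98) {
  if (length(aligned) < 3) stop_thighseg("need at least 3 aligned shapes")
  stopifnot(variance_retained > 0, variance_retained <= 1)
  X <- t(vapply(aligned, shape_vector, numeric(2 * nrow(aligned[[1]]$points))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  n <- nrow(X)
  lambda <- sv$d^2 / (n - 1)
  keep <- lambda > max(lambda[1], 0) * 1e-10 & seq_along(lambda) <= n - 1
  lambda <- lambda[keep]
  V <- sv$v[, keep, drop = FALSE]
  if (length(lambda) == 0) {
    m <- 0L
  } else {
    cum <- cumsum(lambda) / sum(lambda)
    m <- which(cum >= variance_retained - 1e-12)[1]
  }
  structure(list(
    mean = mu,
    modes = V[, seq_len(m), drop = FALSE],
    eigenvalues = lambda[seq_len(m)],
    variance_retained = variance_retained,
    total_variance = sum(lambda),
    component = aligned[[1]]$component,
    P = nrow(aligned[[1]]$points)
  ), class = "thigh_pdm")
}

#' @export
print.thigh_pdm <- function(x, ...) {
  cat(sprintf("<thigh_pdm: P = %d, %d modes (%.1f%% variance retained)>\n",
              x$P, length(x$eigenvalues),
              100 * sum(x$eigenvalues) / max(x$total_variance, .Machine$double.eps)))
  invisible(x)
}

# model-frame instance points for mode weights b
pdm_instance <- function(model, b = NULL) {
  v <- model$mean
  if (length(model$eigenvalues) > 0 && !is.null(b))
    v <- v + model$modes %*% b
  vector_to_points(v)
}

# outward unit normals per point, computed per closed component outline;
# outward = away from the component centroid
outline_normals <- function(pts, component) {
  nrm <- matrix(0, nrow(pts), 2)
  for (comp in levels(component)) {
    idx <- which(component == comp)
    p <- pts[idx, , drop = FALSE]
    n <- nrow(p)
    prv <- c(n, seq_len(n - 1)); nxt <- c(seq_len(n)[-1], 1)
    tang <- p[nxt, , drop = FALSE] - p[prv, , drop = FALSE]
    len <- sqrt(rowSums(tang^2)); len[len < 1e-12] <- 1
    tang <- tang / len
    nn <- cbind(tang[, 2], -tang[, 1])
    ctr <- colMeans(p)
    flip <- rowSums(nn * sweep(p, 2, ctr)) < 0
    nn[flip, ] <- -nn[flip, ]
    nrm[idx, ] <- nn
  }
  nrm
}

#' Train the gray-level profile model
#'
#' For every shape point, the mean and (ridge-regularized) covariance of the
#' normalized first-derivative intensity profile sampled at unit steps along
#' the outward outline normal, over a set of training images with matching
#' shapes in image coordinates. Images are expected preprocessed (equalized,
#' 2 x 2 median filtered, range normalized); samples falling outside the
#' image are edge-replicated.
#'
#' @param images List of [grayscale_image] (or matrices).
#' @param shapes List of [thigh_shape] in image coordinates, same length.
#' @param k Profile half-length in pixels (profile length `2k + 1`).
#' @return Object of class `thigh_profiles`: `k`, `means` (P x (2k+1)),
#'   `invcov` (array (2k+1, 2k+1, P)), `component`.
#' @export
train_profiles <- function(images, shapes, k = 6) {
  stopifnot(length(images) == length(shapes), length(images) >= 1, k >= 1)
  P <- nrow(shapes[[1]]$points)
  L <- 2 * k + 1
  acc <- array(0, c(length(images), P, L))
  for (i in seq_along(images)) {
    img <- as_image_matrix(images[[i]])
    acc[i, , ] <- sample_profiles(img, shapes[[i]]$points,
                                  outline_normals(shapes[[i]]$points, shapes[[i]]$component), k)
  }
  means <- matrix(0, P, L)
  invcov <- array(0, c(L, L, P))
  for (p in seq_len(P)) {
    G <- acc[, p, , drop = TRUE]
    if (is.null(dim(G))) G <- matrix(G, 1, L)
    mu <- colMeans(G)
    cv <- if (nrow(G) > 1) stats::cov(G) else matrix(0, L, L)
    eps <- max(1e-4 * sum(diag(cv)) / L, 1e-10)
    cv <- cv + diag(eps, L)
    means[p, ] <- mu
    invcov[, , p] <- solve(cv)
  }
  structure(list(k = k, means = means, invcov = invcov,
                 component = shapes[[1]]$component, P = P),
            class = "thigh_profiles")
}

# normalized derivative profiles at given points/normals; returns P x (2k+1)
# (vectorized over all points and sample offsets)
sample_profiles <- function(img, pts, normals, k) {
  off <- -(k + 1):(k + 1)          # 2k + 3 raw samples
  P <- nrow(pts)
  X <- outer(normals[, 1], off) + pts[, 1]
  Y <- outer(normals[, 2], off) + pts[, 2]
  raw <- matrix(bilinear_sample(img, as.vector(X), as.vector(Y)), P)
  L <- 2 * k + 1
  g <- (raw[, 3:(L + 2), drop = FALSE] - raw[, 1:L, drop = FALSE]) / 2
  norm <- rowSums(abs(g)) + 1e-12
  g / norm
}

#' Read / write shapes as CSV
#'
#' Column layout: `component, point_index, col, row` (0-based points in
#' image coordinates).
#'
#' @param shape A [thigh_shape].
#' @param path CSV file path.
#' @return `path` invisibly, or the [thigh_shape] read back.
#' @export
write_shape_csv <- function(shape, path) {
  utils::write.csv(data.frame(
    component = as.character(shape$component),
    point_index = seq_len(nrow(shape$points)) - 1L,
    col = shape$points[, 1], row = shape$points[, 2]
  ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shape_csv
#' @export
read_shape_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(match(df$component, unique(df$component)), df$point_index), ]
  thigh_shape(cbind(df$col, df$row), df$component)
}
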