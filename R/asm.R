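# Iterative active shape model search and shape-to-mask conversion.

#' Fit the active shape model to an image
#'
#' Classic iterative ASM search: each iteration (1) proposes, for every
#' point, the offset along the outline normal (within `search_range` pixels)
#' whose normalized-derivative profile minimizes the Mahalanobis distance to
#' that point's profile model, (2) updates the similarity pose by a
#' Procrustes fit of the current model instance to the proposals and (3)
#' updates the mode weights by projecting the pose-removed proposals onto the
#' modes, hard-clamped to three standard deviations (`|b_j| <= 3 sqrt(lambda_j)`).
#' The search is deterministic: identical inputs give identical results.
#'
#' @param model A [train_pdm()] model.
#' @param profiles A [train_profiles()] appearance model with matching P.
#' @param img Preprocessed [grayscale_image] or matrix (equalized, 2 x 2
#'   median filtered, range normalized).
#' @param init A [pose()] placing the model mean shape in the image.
#' @param n_iter Number of search iterations (default 30).
#' @param search_range Normal search half-range in pixels.
#' @return List with `shape` (fitted [thigh_shape] in image coordinates),
#'   `b` (mode weights), `pose` (final [pose()]).
#' @export
fit_asm <- function(model, profiles, img, init, n_iter = 30, search_range = 8) {
  if (model$P != profiles$P) stop_thighseg("model and profiles disagree on P")
  if (n_iter < 0) stop_thighseg("n_iter must be >= 0")
  px <- as_image_matrix(img)
  nr <- nrow(px); nc <- ncol(px)
  m <- length(model$eigenvalues)
  b <- rep(0, m)
  cur_pose <- init
  comp <- model$component
  k <- profiles$k
  offs <- -search_range:search_range
  check_bounds <- function(pts) {
    if (any(pts[, 1] < 0 | pts[, 1] > nc - 1 | pts[, 2] < 0 | pts[, 2] > nr - 1))
      stop_thighseg("shape escaped image bounds during ASM search ",
                    sprintf("(x range %.1f..%.1f, y range %.1f..%.1f)",
                            min(pts[, 1]), max(pts[, 1]), min(pts[, 2]), max(pts[, 2])))
  }
  Xm <- pdm_instance(model, b)
  X <- apply_pose(Xm, cur_pose)
  check_bounds(X)
  if (n_iter > 0) for (it in seq_len(n_iter)) {
    nrm <- outline_normals(X, comp)
    best <- best_profile_offsets(px, X, nrm, profiles, offs)
    Y <- X + best * nrm
    cur_pose <- fit_similarity(Xm, Y)
    if (m > 0) {
      yp <- apply_pose(Y, invert_pose(cur_pose))
      b <- drop(crossprod(model$modes, c(yp[, 1], yp[, 2]) - model$mean))
      lim <- 3 * sqrt(model$eigenvalues)
      b <- pmin(pmax(b, -lim), lim)
    }
    Xm <- pdm_instance(model, b)
    X <- apply_pose(Xm, cur_pose)
    check_bounds(X)
  }
  list(shape = thigh_shape(X, comp), b = b, pose = cur_pose)
}

# per point, the normal offset minimizing the Mahalanobis profile distance
best_profile_offsets <- function(img, pts, normals, profiles, offs) {
  P <- nrow(pts)
  k <- profiles$k
  L <- 2 * k + 1
  no <- length(offs)
  samp <- -(k + 1):(k + 1)
  # sample coordinates for all points x candidate offsets x profile samples
  steps <- rep(offs, each = length(samp)) + rep(samp, times = no)  # nv values
  X <- pts[, 1] + outer(normals[, 1], steps)
  Y <- pts[, 2] + outer(normals[, 2], steps)
  raw <- matrix(bilinear_sample(img, as.vector(X), as.vector(Y)), P)
  best <- numeric(P)
  for (p in seq_len(P)) {
    R <- matrix(raw[p, ], nrow = length(samp))          # samples x offsets
    g <- (R[3:(L + 2), , drop = FALSE] - R[1:L, , drop = FALSE]) / 2
    g <- sweep(g, 2, colSums(abs(g)) + 1e-12, "/")
    D <- g - profiles$means[p, ]
    q <- colSums(D * (profiles$invcov[, , p] %*% D))
    best[p] <- offs[which.min(q)]
  }
  best
}

#' Rasterize a fitted shape into per-component masks
#'
#' Each component's closed outline is filled with the pixel-center even-odd
#' rule. The femoral cortex mask is the femur-circumference fill minus the
#' medulla fill.
#'
#' @param shape A [thigh_shape] in image coordinates.
#' @param nr,nc Grid size.
#' @return Named list of 0/1 matrices: one per shape component plus
#'   `femur_cortex`.
#' @export
shape_to_masks <- function(shape, nr, nc) {
  masks <- list()
  for (comp in levels(shape$component)) {
    pts <- shape$points[shape$component == comp, , drop = FALSE]
    masks[[comp]] <- fill_polygon(pts, nr, nc)
  }
  if (!is.null(masks$femur) && !is.null(masks$medulla))
    masks$femur_cortex <- ((masks$femur == 1) & (masks$medulla == 0)) + 0L
  masks
}

#' Initialization pose from a reference shape
#'
#' Similarity Procrustes fit of the model mean shape onto a reference shape
#' in image coordinates — the programmatic surrogate for the manual placement
#' of the model on the femoral bone / gracilis landmarks.
#'
#' @param model A [train_pdm()] model.
#' @param reference A [thigh_shape] in image coordinates.
#' @return A [pose()].
#' @export
init_pose_from_shape <- function(model, reference) {
  fit_similarity(pdm_instance(model), reference$points)
}

#' Perturb a pose
#'
#' Adds a translation, rotation and relative scale offset — used to emulate
#' imprecise manual model placement.
#'
#' @param p A [pose()].
#' @param dx,dy Translation offsets (px).
#' @param dtheta Rotation offset (radians).
#' @param dscale Relative scale offset (e.g. `0.05` for +5%).
#' @return A [pose()].
#' @export
perturb_pose <- function(p, dx = 0, dy = 0, dtheta = 0, dscale = 0) {
  pose(p$tx + dx, p$ty + dy, p$s * (1 + dscale), p$theta + dtheta)
}

#' Save a trained shape model archive
#'
#' Writes a directory with `model.json` (layout metadata, version field) and
#' raw little-endian float64 arrays for the mean, modes, eigenvalues and
#' profile statistics.
#'
#' @param model A [train_pdm()] model.
#' @param profiles A [train_profiles()] model.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_model_archive <- function(model, profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wbin <- function(x, f)
    writeBin(as.numeric(x), file.path(dir, f), size = 8, endian = "little")
  wbin(model$mean, "mean.f64")
  wbin(model$modes, "modes.f64")
  wbin(model$eigenvalues, "eigenvalues.f64")
  wbin(profiles$means, "profile_means.f64")
  wbin(profiles$invcov, "profile_invcov.f64")
  meta <- list(
    format = "thighseg-model", version = 1L,
    P = model$P, n_modes = length(model$eigenvalues),
    variance_retained = model$variance_retained,
    total_variance = model$total_variance,
    profile_k = profiles$k,
    component = as.character(model$component)
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a shape model archive
#'
#' @param dir Directory written by [save_model_archive()].
#' @return List with `model` and `profiles`.
#' @export
load_model_archive <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "thighseg-model"))
    stop_thighseg("not a thighseg model archive: ", dir)
  rbin <- function(f, n)
    readBin(file.path(dir, f), "numeric", n = n, size = 8, endian = "little")
  P <- meta$P; m <- meta$n_modes; L <- 2 * meta$profile_k + 1
  comp <- factor(meta$component, levels = unique(meta$component))
  model <- structure(list(
    mean = rbin("mean.f64", 2 * P),
    modes = matrix(rbin("modes.f64", 2 * P * m), 2 * P, m),
    eigenvalues = rbin("eigenvalues.f64", m),
    variance_retained = meta$variance_retained,
    total_variance = meta$total_variance,
    component = comp, P = P
  ), class = "thigh_pdm")
  profiles <- structure(list(
    k = meta$profile_k,
    means = matrix(rbin("profile_means.f64", P * L), P, L),
    invcov = array(rbin("profile_invcov.f64", L * L * P), c(L, L, P)),
    component = comp, P = P
  ), class = "thigh_profiles")
  list(model = model, profiles = profiles)
}
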