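# Active-contour (snake) refinement of component outlines.

#' Snake parameters
#'
#' @param alpha Elasticity weight (>= 0).
#' @param beta Rigidity weight (>= 0).
#' @param gamma Step size (> 0).
#' @param sigma_ext Gaussian smoothing (px) of the image before the external
#'   (edge) energy is computed.
#' @param max_iter Iteration cap (>= 1).
#' @param tol Convergence threshold on mean point movement (px).
#' @return Object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.4, beta = 10.0, gamma = 1.0,
                         sigma_ext = 0.7, max_iter = 200, tol = 0.1) {
  stopifnot(alpha >= 0, beta >= 0, gamma > 0, max_iter >= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 sigma_ext = sigma_ext, max_iter = max_iter, tol = tol),
            class = "snake_params")
}

#' Per-component snake parameter table
#'
#' Elasticity/rigidity defaults: `alpha = 0.4`, `beta = 10.0` for the thigh
#' circumference, femur, medulla, muscle hull (fascia), quadriceps, gracilis
#' and sartorius, and `alpha = 0.9`, `beta = 0.5` for the hamstrings to
#' account for their stronger boundary curvature. The femur circumference and
#' the medulla carry a two-stage flag: their contours are first evolved on a
#' 6 x 6 median-filtered image and then refined on the unfiltered image.
#'
#' @param overrides Optional named list of [snake_params()] replacing
#'   individual component entries.
#' @return Named list (one entry per [SHAPE_COMPONENTS]) of `snake_params`,
#'   each with an extra logical field `two_stage`.
#' @export
component_param_table <- function(overrides = NULL) {
  tab <- list()
  for (comp in SHAPE_COMPONENTS) {
    p <- if (comp == "hamstrings") snake_params(alpha = 0.9, beta = 0.5)
         else snake_params(alpha = 0.4, beta = 10.0)
    p$two_stage <- comp %in% c("femur", "medulla")
    tab[[comp]] <- p
  }
  if (!is.null(overrides)) for (nm in names(overrides)) {
    p <- overrides[[nm]]
    if (is.null(p$two_stage)) p$two_stage <- nm %in% c("femur", "medulla")
    tab[[nm]] <- p
  }
  tab
}

#' External (image) energy for active contours
#'
#' Potential `-|grad(G_sigma * I)|` rescaled to `[-1, 0]` and its force field
#' `-grad(potential)` by central differences with replicated (zero-flux)
#' borders. Snakes descend this potential toward strong edges.
#'
#' @param img [grayscale_image] or matrix (normalized).
#' @param sigma_ext Gaussian smoothing in px.
#' @return List with `potential`, `fx`, `fy` (matrices).
#' @export
external_energy <- function(img, sigma_ext = 1.0) {
  px <- as_image_matrix(img)
  sm <- gaussian_smooth(px, sigma_ext)
  g <- central_gradient(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  pot <- if (mx > 0) -mag / mx else mag * 0
  f <- central_gradient(pot)
  list(potential = pot, fx = -f$gx, fy = -f$gy)
}

# internal-energy system matrix for a closed snake of n points
snake_system <- function(n, alpha, beta, gamma) {
  idx <- function(i) ((i - 1) %% n) + 1
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, idx(i - 1)] <- A[i, idx(i - 1)] - alpha
    A[i, i] <- A[i, i] + 2 * alpha
    A[i, idx(i + 1)] <- A[i, idx(i + 1)] - alpha
    A[i, idx(i - 2)] <- A[i, idx(i - 2)] + beta
    A[i, idx(i - 1)] <- A[i, idx(i - 1)] - 4 * beta
    A[i, i] <- A[i, i] + 6 * beta
    A[i, idx(i + 1)] <- A[i, idx(i + 1)] - 4 * beta
    A[i, idx(i + 2)] <- A[i, idx(i + 2)] + beta
  }
  solve(diag(n) + gamma * A)
}

#' Evolve a closed contour against image forces
#'
#' Standard semi-implicit closed-snake update: the pentadiagonal internal
#' energy system (weights `alpha`, `beta`) is solved implicitly while the
#' external force is sampled bilinearly at the current points. The contour is
#' resampled to uniform arc length every 5 iterations; evolution stops when
#' the mean point movement drops below `tol` or after `max_iter` iterations.
#' Deterministic: no randomness in the update.
#'
#' @param contour N x 2 matrix (closed polyline, `N >= 8`), 0-based
#'   `(col, row)`.
#' @param img [grayscale_image] or matrix.
#' @param params A [snake_params()].
#' @param ext Optional precomputed [external_energy()] of `img`.
#' @return Evolved N x 2 contour matrix.
#' @export
evolve_contour <- function(contour, img, params, ext = NULL) {
  px <- as_image_matrix(img)
  nr <- nrow(px); nc <- ncol(px)
  x <- as.matrix(contour)
  if (nrow(x) < 8) stop_thighseg("contour needs at least 8 points")
  n <- nrow(x)
  if (is.null(ext)) ext <- external_energy(px, params$sigma_ext)
  Ainv <- snake_system(n, params$alpha, params$beta, params$gamma)
  clamped <- FALSE
  for (it in seq_len(params$max_iter)) {
    fx <- bilinear_sample(ext$fx, x[, 1], x[, 2])
    fy <- bilinear_sample(ext$fy, x[, 1], x[, 2])
    xn <- Ainv %*% (x + params$gamma * cbind(fx, fy))
    if (any(xn[, 1] < 0 | xn[, 1] > nc - 1 | xn[, 2] < 0 | xn[, 2] > nr - 1)) {
      clamped <- TRUE
      xn[, 1] <- pmin(pmax(xn[, 1], 0), nc - 1)
      xn[, 2] <- pmin(pmax(xn[, 2], 0), nr - 1)
    }
    move <- mean(sqrt(rowSums((xn - x)^2)))
    x <- xn
    if (it %% 5 == 0) x <- resample_closed(x, n)
    if (move < params$tol) break
  }
  if (clamped) warning("contour clamped to image bounds", call. = FALSE)
  x
}

# total snake energy (internal + sampled potential), used by invariant tests
snake_energy <- function(contour, ext, alpha, beta) {
  n <- nrow(contour)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  d1 <- contour[nxt, ] - contour
  d2 <- contour[nxt, ] - 2 * contour + contour[prv, ]
  internal <- 0.5 * (alpha * sum(d1^2) + beta * sum(d2^2))
  external <- sum(bilinear_sample(ext$potential, contour[, 1], contour[, 2]))
  internal + external
}

#' Refine component masks with active contours
#'
#' Each component's mask boundary (largest connected component) is extracted,
#' resampled to uniform arc length, evolved with the component's snake
#' parameters and re-rasterized. Two-stage components (femur circumference,
#' medulla) are evolved first on a 6 x 6 median-filtered copy of the image
#' and then refined on the unfiltered image.
#'
#' @param masks Named list of 0/1 matrices (shape components, as produced by
#'   [shape_to_masks()]).
#' @param img_unfiltered [grayscale_image] or matrix the contours attach to.
#' @param table A [component_param_table()].
#' @param spacing_px Target contour point spacing in px (controls N).
#' @return Named list of refined 0/1 masks (same names as the input that
#'   match a table entry; other entries are passed through).
#' @export
refine_components <- function(masks, img_unfiltered, table = component_param_table(),
                              spacing_px = 1) {
  px <- as_image_matrix(img_unfiltered)
  nr <- nrow(px); nc <- ncol(px)
  filtered <- NULL
  ext_cache <- new.env(parent = emptyenv())
  get_ext <- function(im, key, sigma) {
    k <- paste0(key, "_", sigma)
    if (is.null(ext_cache[[k]])) ext_cache[[k]] <- external_energy(im, sigma)
    ext_cache[[k]]
  }
  out <- masks
  for (comp in names(masks)) {
    params <- table[[comp]]
    if (is.null(params)) next
    m <- masks[[comp]]
    if (sum(m) == 0) {
      warning("empty mask for component ", comp, call. = FALSE)
      next
    }
    bnd <- mask_boundary(m)
    if (is.null(bnd) || nrow(bnd) < 8) next
    per <- sum(sqrt(rowSums(diff(rbind(bnd, bnd[1, ]))^2)))
    # small outlines get a dense floor: the discrete internal forces scale
    # with (2 pi / n)^2, so too few points biases small contours inward
    n <- max(96L, min(400L, round(per / spacing_px)))
    ctr <- resample_closed(bnd, n)
    if (isTRUE(params$two_stage)) {
      if (is.null(filtered)) filtered <- median_filter(px, 6)
      ctr <- evolve_contour(ctr, filtered, params,
                            ext = get_ext(filtered, "filt", params$sigma_ext))
    }
    ctr <- evolve_contour(ctr, px, params,
                          ext = get_ext(px, "raw", params$sigma_ext))
    ref <- contour_to_mask(ctr, nr, nc)
    out[[comp]] <- largest_component(ref)
  }
  if (!is.null(out$femur) && !is.null(out$medulla))
    out$femur_cortex <- ((out$femur == 1) & (out$medulla == 0)) + 0L
  out
}
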