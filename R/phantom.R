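# Seeded synthetic thigh-phantom generator: T1-like cross-section images with
# ground-truth shapes, label maps and optional longitudinal area change.

ellipse_points <- function(cx, cy, ax, ay, n) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(cx + ax * cos(th), cy + ay * sin(th))
}

# canonical template geometry on a 256 grid, scaled to the requested grid
phantom_template <- function(grid = 256, points_per_component = 40) {
  sc <- grid / 256
  n <- points_per_component
  outlines <- list(
    thigh      = ellipse_points(128, 128, 95, 95, n),
    fascia     = ellipse_points(128, 126, 72, 74, n),
    femur      = ellipse_points(122, 110, 13, 13, n),
    medulla    = ellipse_points(122, 110, 8, 8, n),
    quadriceps = ellipse_points(128, 75, 42, 15, n),
    hamstrings = ellipse_points(120, 172, 36, 16, n),
    sartorius  = ellipse_points(180, 120, 8, 8, n),
    gracilis   = ellipse_points(172, 158, 9, 9, n)
  )
  outlines <- lapply(outlines, function(p) p * sc)
  adductor <- ellipse_points(80, 150, 16, 12, n) * sc
  list(outlines = outlines, adductor = adductor, center = c(128, 128) * sc,
       scale = sc)
}

# displacement fields of the built-in 4-mode generative shape model, per unit
# (1 SD) amplitude: global size, SCF ring thickness (fascia + inner anatomy
# vs fixed thigh), quadriceps/hamstrings balance, femoral offset
phantom_mode_displacements <- function(tmpl) {
  ctr <- tmpl$center
  rel <- function(p) sweep(p, 2, ctr)
  zero <- function(p) p * 0
  inner <- c("fascia", "femur", "medulla", "quadriceps", "hamstrings",
             "sartorius", "gracilis")
  d <- list()
  d[[1]] <- list(
    outlines = lapply(tmpl$outlines, function(p) 0.05 * rel(p)),
    adductor = 0.05 * rel(tmpl$adductor)
  )
  d[[2]] <- list(
    outlines = lapply(names(tmpl$outlines), function(nm) {
      if (nm %in% inner) 0.04 * rel(tmpl$outlines[[nm]])
      else zero(tmpl$outlines[[nm]])
    }),
    adductor = 0.04 * rel(tmpl$adductor)
  )
  names(d[[2]]$outlines) <- names(tmpl$outlines)
  d[[3]] <- list(
    outlines = lapply(names(tmpl$outlines), function(nm) {
      p <- tmpl$outlines[[nm]]
      if (nm == "quadriceps") 0.05 * sweep(p, 2, colMeans(p))
      else if (nm == "hamstrings") -0.05 * sweep(p, 2, colMeans(p))
      else zero(p)
    }),
    adductor = zero(tmpl$adductor)
  )
  names(d[[3]]$outlines) <- names(tmpl$outlines)
  shift <- c(2.5, 1.5) * tmpl$scale
  d[[4]] <- list(
    outlines = lapply(names(tmpl$outlines), function(nm) {
      p <- tmpl$outlines[[nm]]
      if (nm %in% c("femur", "medulla"))
        matrix(shift, nrow(p), 2, byrow = TRUE)
      else zero(p)
    }),
    adductor = zero(tmpl$adductor)
  )
  names(d[[4]]$outlines) <- names(tmpl$outlines)
  d
}

# nesting / disjointness invariants; returns TRUE or a message string
check_anatomy <- function(geom) {
  o <- geom$outlines
  inside <- function(a, b) all(points_in_polygon(a, b))
  if (!inside(o$medulla, o$femur)) return("medulla not inside femur")
  if (!inside(o$femur, o$fascia)) return("femur not inside fascia")
  if (!inside(o$fascia, o$thigh)) return("fascia not inside thigh")
  members <- c("quadriceps", "hamstrings", "sartorius", "gracilis")
  for (nm in members)
    if (!inside(o[[nm]], o$fascia)) return(paste(nm, "not inside fascia"))
  if (!inside(geom$adductor, o$fascia)) return("adductors not inside fascia")
  regions <- c(o[members], list(femur = o$femur, adductor = geom$adductor))
  nms <- names(regions)
  for (i in seq_along(regions)) for (j in seq_len(i - 1)) {
    if (any(points_in_polygon(regions[[i]], regions[[j]])) ||
        any(points_in_polygon(regions[[j]], regions[[i]])))
      return(paste(nms[i], "overlaps", nms[j]))
  }
  TRUE
}

#' T1-like class intensity model
#'
#' Per-class mean/SD of normalized intensity (fat bright, muscle
#' intermediate, cortical bone dark, medulla bright), plus global additive
#' Gaussian noise and an optional smooth multiplicative bias field.
#'
#' @param fat,muscle,cortex,medulla,background Length-2 `(mean, sd)` in
#'   normalized units.
#' @param noise_sd Global additive noise SD.
#' @param bias_amp Amplitude of the multiplicative bias field (0 = off).
#' @return Object of class `intensity_model`.
#' @export
intensity_model <- function(fat = c(0.80, 0.05), muscle = c(0.35, 0.04),
                            cortex = c(0.10, 0.02), medulla = c(0.75, 0.05),
                            background = c(0.05, 0.01),
                            noise_sd = 0.01, bias_amp = 0) {
  im <- list(fat = fat, muscle = muscle, cortex = cortex, medulla = medulla,
             background = background, noise_sd = noise_sd, bias_amp = bias_amp)
  stopifnot(all(vapply(im[1:5], function(v) v[1] >= 0 && v[1] <= 1 && v[2] >= 0, TRUE)))
  structure(im, class = "intensity_model")
}

#' Sample a phantom anatomy
#'
#' Draws mode amplitudes from the built-in 4-mode generative shape model
#' (truncated at 3 SD), applies the linear displacement fields to the
#' canonical template, places 2–6 sub-threshold vessel dots in the residual
#' region and enforces the nesting invariants (resampling up to 10 times).
#'
#' @param seed Optional seed (uses the ambient RNG stream when `NULL`).
#' @param b Optional fixed mode amplitudes (length 4, in SD units); `b = 0`
#'   returns the canonical template exactly.
#' @param variation Per-mode SD multipliers.
#' @param grid Image side in pixels.
#' @param points_per_component Outline points per component.
#' @return Object of class `thigh_anatomy`: `outlines` (8 matrices),
#'   `adductor`, `vessels` (data.frame x/y/r), `pose`, `b`, `grid`,
#'   `spacing`.
#' @export
sample_anatomy <- function(seed = NULL, b = NULL, variation = c(1, 1, 1, 1),
                           grid = 256, points_per_component = 40) {
  if (!is.null(seed))
    return(withr::with_seed(seed, sample_anatomy(NULL, b, variation, grid,
                                                 points_per_component)))
  tmpl <- phantom_template(grid, points_per_component)
  modes <- phantom_mode_displacements(tmpl)
  fixed_b <- !is.null(b)
  if (fixed_b && any(abs(b) > 3 * pmax(variation, 1e-12)))
    stop_thighseg("mode amplitudes must lie within 3 SD")
  for (attempt in seq_len(10)) {
    bb <- if (fixed_b) b else pmin(pmax(stats::rnorm(4, 0, variation),
                                        -3 * variation), 3 * variation)
    outlines <- tmpl$outlines
    adductor <- tmpl$adductor
    for (j in 1:4) {
      outlines <- Map(function(p, d) p + bb[j] * d, outlines, modes[[j]]$outlines)
      adductor <- adductor + bb[j] * modes[[j]]$adductor
    }
    geom <- structure(list(
      outlines = outlines, adductor = adductor,
      vessels = NULL, pose = pose(), b = bb, grid = grid,
      points_per_component = points_per_component,
      spacing = rep(0.98 * 256 / grid, 2)
    ), class = "thigh_anatomy")
    ok <- check_anatomy(geom)
    if (isTRUE(ok)) {
      geom$vessels <- sample_vessels(geom)
      return(geom)
    }
    if (fixed_b) stop_thighseg("anatomy invariant violated: ", ok)
  }
  stop_thighseg("could not sample a valid anatomy in 10 attempts (last: ", ok, ")")
}

# vessel dots: 2-6 muscle-like circles below the connected-size threshold,
# rejection-sampled inside the residual region
sample_vessels <- function(geom) {
  sc <- geom$grid / 256
  nv <- sample(2:6, 1)
  out <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  obstacles <- c(geom$outlines[c("femur", "quadriceps", "hamstrings",
                                 "sartorius", "gracilis")],
                 list(geom$adductor))
  fascia <- geom$outlines$fascia
  for (i in seq_len(nv)) {
    for (try in seq_len(100)) {
      r <- stats::runif(1, 2, 4.2) * sc
      ctr <- colMeans(fascia)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.85
      fr <- fascia[sample.int(nrow(fascia), 1), ] - ctr
      cand <- ctr + rad * c(cos(ang), sin(ang)) * sqrt(sum(fr^2))
      m <- matrix(cand, 1, 2)
      if (!points_in_polygon(m, fascia)) next
      mind <- min(sqrt(rowSums(sweep(fascia, 2, cand)^2)))
      for (ob in obstacles)
        mind <- min(mind, sqrt(rowSums(sweep(ob, 2, cand)^2)))
      if (nrow(out) > 0)
        mind <- min(mind, sqrt((out$x - cand[1])^2 + (out$y - cand[2])^2) - out$r)
      if (mind > r + 4 * sc) {
        out <- rbind(out, data.frame(x = cand[1], y = cand[2], r = r))
        break
      }
    }
  }
  out
}

# pose the whole anatomy about the grid center
pose_anatomy <- function(geom, p) {
  ctr <- rep(geom$grid / 2, 2)
  tf <- function(pts) {
    rel <- sweep(pts, 2, ctr)
    sweep(apply_pose(rel, pose(0, 0, p$s, p$theta)), 2,
          ctr + c(p$tx, p$ty), `+`)
  }
  geom$outlines <- lapply(geom$outlines, tf)
  geom$adductor <- tf(geom$adductor)
  if (!is.null(geom$vessels) && nrow(geom$vessels) > 0) {
    vc <- tf(cbind(geom$vessels$x, geom$vessels$y))
    geom$vessels$x <- vc[, 1]; geom$vessels$y <- vc[, 2]
    geom$vessels$r <- geom$vessels$r * p$s
  }
  geom$pose <- p
  geom
}

#' Ground-truth shape of an anatomy
#'
#' @param geom A [sample_anatomy()] geometry (posed or not).
#' @return A [thigh_shape] with the 8 model components in image coordinates.
#' @export
anatomy_shape <- function(geom) {
  pts <- do.call(rbind, geom$outlines[SHAPE_COMPONENTS])
  comp <- factor(rep(SHAPE_COMPONENTS,
                     vapply(geom$outlines[SHAPE_COMPONENTS], nrow, 1L)),
                 levels = SHAPE_COMPONENTS)
  thigh_shape(pts, comp)
}

#' Render a phantom image and its truth label map
#'
#' Rasterizes the geometry with the pixel-center rule into the fixed label
#' code table, then synthesizes a T1-like image: per-class mean intensity
#' plus per-class Gaussian noise plus global noise (and optional bias
#' field), clipped to `[0, 1]`.
#'
#' @param geom A [sample_anatomy()] geometry.
#' @param intensity An [intensity_model()].
#' @param seed Optional seed for the noise draw (ambient RNG when `NULL`).
#' @return List with `image` ([grayscale_image]) and `labels` (integer
#'   matrix).
#' @export
render_image <- function(geom, intensity = intensity_model(), seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, render_image(geom, intensity, NULL)))
  g <- geom$grid
  o <- geom$outlines
  lab <- matrix(0L, g, g)
  paint <- function(poly, code) {
    m <- fill_polygon(poly, g, g)
    lab[m == 1L] <<- code
  }
  paint(o$thigh, LABEL_CODES[["scf"]])
  paint(o$fascia, LABEL_CODES[["imf"]])
  paint(o$quadriceps, LABEL_CODES[["quadriceps"]])
  paint(o$hamstrings, LABEL_CODES[["hamstrings"]])
  paint(o$sartorius, LABEL_CODES[["sartorius"]])
  paint(o$gracilis, LABEL_CODES[["adductors"]])
  paint(geom$adductor, LABEL_CODES[["adductors"]])
  if (!is.null(geom$vessels) && nrow(geom$vessels) > 0) {
    xs <- matrix(rep(0:(g - 1), each = g), g)   # x per pixel (col index)
    ys <- matrix(rep(0:(g - 1), times = g), g)  # y per pixel (row index)
    for (i in seq_len(nrow(geom$vessels))) {
      v <- geom$vessels[i, ]
      sel <- (xs - v$x)^2 + (ys - v$y)^2 <= v$r^2
      lab[sel] <- LABEL_CODES[["other"]]
    }
  }
  paint(o$femur, LABEL_CODES[["femur_cortex"]])
  paint(o$medulla, LABEL_CODES[["medulla"]])
  class_of <- c("background", "fat", "fat", "muscle", "muscle", "muscle",
                "muscle", "cortex", "medulla", "muscle")  # codes 0..9
  cls <- class_of[lab + 1L]
  mu <- vapply(intensity[cls], `[`, numeric(1), 1)
  sdv <- vapply(intensity[cls], `[`, numeric(1), 2)
  img <- matrix(mu + stats::rnorm(g * g) * sdv, g, g)
  if (intensity$noise_sd > 0)
    img <- img + stats::rnorm(g * g, 0, intensity$noise_sd)
  if (intensity$bias_amp > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    xs <- matrix(rep(0:(g - 1), each = g), g)
    ys <- matrix(rep(0:(g - 1), times = g), g)
    bias <- 1 + intensity$bias_amp *
      cos(2 * pi * xs / g + ph[1]) * cos(2 * pi * ys / g + ph[2])
    img <- img * bias
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = grayscale_image(img, geom$spacing, id = "phantom"),
       labels = lab)
}

#' Apply longitudinal area change to an anatomy
#'
#' Scales targeted outlines about their centroids so that the truth area of
#' each targeted structure changes by the requested percentage. Muscle
#' targets scale their own outline; `adductors` scales the gracilis and the
#' extra adductor blob; `imf` rescales the fascia so that the residual
#' (fascia minus muscles and femur) area hits the target; `scf` rescales the
#' thigh so that thigh minus the fascia hull hits the target. Nesting is
#' re-checked and violations raise an error.
#'
#' @param geom A [sample_anatomy()] geometry (unposed).
#' @param targets Named numeric vector of percent changes, names among
#'   `scf`, `imf`, `quadriceps`, `hamstrings`, `adductors`, `sartorius`;
#'   absolute values capped at 25.
#' @return The changed geometry.
#' @export
apply_longitudinal_change <- function(geom, targets) {
  if (length(targets) == 0) return(geom)
  if (any(abs(targets) > 25)) stop_thighseg("per-structure change capped at 25%")
  scale_about_centroid <- function(pts, f) {
    ctr <- colMeans(pts)
    sweep(sweep(pts, 2, ctr) * f, 2, ctr, `+`)
  }
  o <- geom$outlines
  vessel_area <- if (is.null(geom$vessels)) 0 else sum(pi * geom$vessels$r^2)
  inner_area <- function(out, add) {
    polygon_area(out$quadriceps) + polygon_area(out$hamstrings) +
      polygon_area(out$sartorius) + polygon_area(out$gracilis) +
      polygon_area(out$femur) + polygon_area(add) + vessel_area
  }
  hull_area <- function(fascia) {
    h <- grDevices::chull(fascia[, 1], fascia[, 2])
    polygon_area(fascia[h, , drop = FALSE])
  }
  base_imf <- polygon_area(o$fascia) - inner_area(o, geom$adductor)
  base_scf <- polygon_area(o$thigh) - hull_area(o$fascia)
  for (nm in c("quadriceps", "hamstrings", "sartorius")) {
    if (nm %in% names(targets)) {
      f <- sqrt(1 + targets[[nm]] / 100)
      o[[nm]] <- scale_about_centroid(o[[nm]], f)
    }
  }
  adductor <- geom$adductor
  if ("adductors" %in% names(targets)) {
    f <- sqrt(1 + targets[["adductors"]] / 100)
    o$gracilis <- scale_about_centroid(o$gracilis, f)
    adductor <- scale_about_centroid(adductor, f)
  }
  if ("imf" %in% names(targets)) {
    target_imf <- base_imf * (1 + targets[["imf"]] / 100)
    need <- target_imf + inner_area(o, adductor)
    f <- sqrt(need / polygon_area(o$fascia))
    o$fascia <- scale_about_centroid(o$fascia, f)
  }
  if ("scf" %in% names(targets)) {
    target_scf <- base_scf * (1 + targets[["scf"]] / 100)
    need <- target_scf + hull_area(o$fascia)
    f <- sqrt(need / polygon_area(o$thigh))
    o$thigh <- scale_about_centroid(o$thigh, f)
  }
  out <- geom
  out$outlines <- o
  out$adductor <- adductor
  ok <- check_anatomy(out)
  if (!isTRUE(ok)) stop_thighseg("longitudinal change violates nesting: ", ok)
  out
}

#' Generate a seeded phantom cohort
#'
#' Draws `n` independent phantoms (anatomy, whole-anatomy pose, rendered
#' image, truth labels and truth shape). With `longitudinal`, a paired
#' follow-up dataset is generated whose per-subject percent changes are
#' drawn from the configured mean/SD per structure (truncated at 25%),
#' re-rendered with fresh noise at the same pose. Bit-reproducible from
#' `(seed, parameters)`.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param variation Per-mode SD multipliers of the generative shape model.
#' @param intensity An [intensity_model()].
#' @param grid Image side (px); spacing scales so the field of view is
#'   constant.
#' @param points_per_component Outline points per component.
#' @param pose_sd List with `t` (translation SD px), `theta` (rotation SD
#'   rad), `log_s` (log-scale SD) for the whole-anatomy pose.
#' @param longitudinal Optional list with named vectors `mean` and `sd`
#'   (percent change per structure).
#' @return A `phantom_dataset` (list of subjects with fields `image`,
#'   `labels`, `shape`, `pose`, `geom`), or, with `longitudinal`, a list
#'   with `baseline` and `followup` datasets.
#' @export
generate_cohort <- function(n, seed, variation = c(1, 1, 1, 1),
                            intensity = intensity_model(), grid = 256,
                            points_per_component = 40,
                            pose_sd = list(t = 4, theta = 4 * pi / 180,
                                           log_s = 0.03),
                            longitudinal = NULL) {
  stopifnot(n >= 1)
  params <- list(variation = variation, grid = grid,
                 points_per_component = points_per_component,
                 pose_sd = pose_sd, longitudinal = longitudinal)
  withr::with_seed(as.integer(seed), {
    base <- vector("list", n)
    fu <- if (!is.null(longitudinal)) vector("list", n)
    changes <- if (!is.null(longitudinal)) matrix(
      0, n, length(longitudinal$mean),
      dimnames = list(NULL, names(longitudinal$mean)))
    sc <- grid / 256
    for (i in seq_len(n)) {
      geom <- sample_anatomy(NULL, NULL, variation, grid, points_per_component)
      p <- pose(stats::rnorm(1, 0, pose_sd$t * sc),
                stats::rnorm(1, 0, pose_sd$t * sc),
                exp(stats::rnorm(1, 0, pose_sd$log_s)),
                stats::rnorm(1, 0, pose_sd$theta))
      posed <- pose_anatomy(geom, p)
      rend <- render_image(posed, intensity)
      base[[i]] <- list(image = rend$image, labels = rend$labels,
                        shape = anatomy_shape(posed), pose = p, geom = posed,
                        id = sprintf("phantom_%03d", i))
      if (!is.null(longitudinal)) {
        # per-subject draw, rejected and redrawn when the resulting
        # geometry cannot satisfy the nesting invariants
        geom2 <- NULL
        for (attempt in 1:10) {
          pct <- stats::rnorm(length(longitudinal$mean), longitudinal$mean,
                              longitudinal$sd)
          pct <- pmin(pmax(pct, -25), 25)
          names(pct) <- names(longitudinal$mean)
          geom2 <- tryCatch(apply_longitudinal_change(geom, pct),
                            error = function(e) NULL)
          if (!is.null(geom2)) break
        }
        if (is.null(geom2))
          stop_thighseg("could not draw a feasible longitudinal change in 10 attempts")
        changes[i, ] <- pct
        posed2 <- pose_anatomy(geom2, p)
        rend2 <- render_image(posed2, intensity)
        fu[[i]] <- list(image = rend2$image, labels = rend2$labels,
                        shape = anatomy_shape(posed2), pose = p, geom = posed2,
                        true_change = pct, id = sprintf("phantom_%03d", i))
      }
    }
    mk <- function(subjects) structure(
      list(subjects = subjects, seed = as.integer(seed), params = params),
      class = "phantom_dataset")
    if (is.null(longitudinal)) mk(base)
    else list(baseline = mk(base), followup = mk(fu), true_changes = changes)
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset: %d subjects, grid %d, seed %d>\n",
              length(x$subjects), x$params$grid, x$seed))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Images as 16-bit TIFF, truth labels as 8-bit PNG plus the code table in
#' the manifest, truth shapes as CSV (`component,point_index,col,row`), and
#' a manifest JSON.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = dataset$seed, n = length(dataset$subjects),
                   grid = dataset$params$grid,
                   spacing = dataset$subjects[[1]]$image$spacing,
                   code_table = as.list(LABEL_CODES))
  for (s in dataset$subjects) {
    save_image(s$image, file.path(dir, paste0(s$id, ".tif")))
    png::writePNG(s$labels / 255, file.path(dir, paste0(s$id, "_labels.png")))
    write_shape_csv(s$shape, file.path(dir, paste0(s$id, "_shape.csv")))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
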