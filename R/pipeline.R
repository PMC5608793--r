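# Full segmentation pipeline: preprocess -> ASM fit -> ACM refine ->
# compartments -> label map, and the longitudinal experiment driver.

#' Pipeline configuration
#'
#' All defaults reproduce the method's reference settings: 30 ASM
#' iterations, the per-component elasticity/rigidity table, the 70-pixel
#' connected-size rule. Manual model placement is replaced by an explicit
#' initialization pose (or a perturbation of the truth-derived pose in
#' experiments); the manual nudge loop is replaced by the replayable
#' `init_perturb` record.
#'
#' @param tiles,clip Adaptive equalization settings.
#' @param n_asm_iterations ASM search iterations.
#' @param search_range ASM normal search half-range (px).
#' @param profile_k Profile half-length (px).
#' @param variance_retained PCA variance fraction retained at training.
#' @param refine Run the active-contour refinement stage.
#' @param snake_overrides Named list of [snake_params()] overriding the
#'   default [component_param_table()].
#' @param literal_threshold Use the printed threshold inequality verbatim
#'   instead of nearest-class-mean assignment.
#' @param min_adductor_px Connected-size cut for the adductor rule.
#' @param init_perturb List `dx`, `dy`, `dtheta`, `dscale` applied to the
#'   initialization pose (user-interaction surrogate, replayable).
#' @param debug_dir Directory for per-stage intermediate outputs (`NULL` =
#'   off): preprocessed images, fitted shape, per-component masks.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(tiles = c(8, 8), clip = 0.01,
                            n_asm_iterations = 30, search_range = 8,
                            profile_k = 6, variance_retained = 0.98,
                            refine = TRUE, snake_overrides = NULL,
                            literal_threshold = FALSE, min_adductor_px = 70,
                            init_perturb = list(dx = 0, dy = 0, dtheta = 0,
                                                dscale = 0),
                            debug_dir = NULL) {
  structure(list(tiles = tiles, clip = clip,
                 n_asm_iterations = n_asm_iterations,
                 search_range = search_range, profile_k = profile_k,
                 variance_retained = variance_retained, refine = refine,
                 snake_overrides = snake_overrides,
                 literal_threshold = literal_threshold,
                 min_adductor_px = min_adductor_px,
                 init_perturb = init_perturb,
                 debug_dir = debug_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly, or the re-read [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw))
    if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
  cfg$tiles <- as.numeric(cfg$tiles)
  cfg
}

#' Segment a thigh cross-section
#'
#' Executes the full ordered pipeline on one image: adaptive histogram
#' equalization, 2 x 2 median filtering and range normalization; iterative
#' ASM search from the initialization pose; per-component active-contour
#' refinement (two-stage via a 6 x 6 median filtered image for femur and
#' medulla); subcutaneous fat from the convex hull of the fascia; intensity
#' threshold and the connected-size rule for the residual pixels; label-map
#' assembly with areas in px and cm^2. Deterministic given image, model and
#' configuration.
#'
#' @param img A [grayscale_image].
#' @param model A list with `model` ([train_pdm()]) and `profiles`
#'   ([train_profiles()]), or a path to a [save_model_archive()] directory.
#' @param init A [pose()] placing the model mean in the image (the manual
#'   placement surrogate); `config$init_perturb` is applied on top.
#' @param config A [pipeline_config()].
#' @return A `segmentation_result` with extra fields `shape` (fitted
#'   [thigh_shape]), `masks` (refined component masks), `threshold`
#'   (the `threshold_context`).
#' @export
segment_thigh <- function(img, model, init, config = pipeline_config()) {
  if (is.character(model)) model <- load_model_archive(model)
  pre <- preprocess_image(img, config$tiles, config$clip)
  fitted_img <- pre$fitted$pixels
  nr <- nrow(fitted_img); nc <- ncol(fitted_img)
  ip <- config$init_perturb
  init <- perturb_pose(init, ip$dx %||% 0, ip$dy %||% 0,
                       ip$dtheta %||% 0, ip$dscale %||% 0)
  fit <- fit_asm(model$model, model$profiles, fitted_img, init,
                 n_iter = config$n_asm_iterations,
                 search_range = config$search_range)
  masks <- shape_to_masks(fit$shape, nr, nc)
  if (isTRUE(config$refine)) {
    tab <- component_param_table(config$snake_overrides)
    masks <- refine_components(masks, pre$unfiltered$pixels, tab)
  }
  scf <- derive_scf(masks$thigh, masks$fascia)
  ctx <- compute_threshold(fitted_img, scf, masks$quadriceps,
                           masks$hamstrings,
                           c(pre$pixel_lowest, pre$pixel_highest))
  res <- assign_residual_pixels(fitted_img, masks, masks$fascia, ctx,
                                config$min_adductor_px,
                                config$literal_threshold)
  seg <- assemble_labelmap(c(masks, list(scf = scf)), res$imf,
                           res$adductors, res$other,
                           spacing = img$spacing,
                           settings = unclass(config),
                           provenance = list(image_id = img$id))
  seg$shape <- fit$shape
  seg$b <- fit$b
  seg$pose <- fit$pose
  seg$masks <- c(masks, list(scf = scf))
  seg$threshold <- ctx
  if (!is.null(config$debug_dir)) {
    dd <- config$debug_dir
    dir.create(dd, showWarnings = FALSE, recursive = TRUE)
    save_image(pre$fitted, file.path(dd, "preprocessed.tif"))
    save_image(pre$unfiltered, file.path(dd, "unfiltered.tif"))
    write_shape_csv(fit$shape, file.path(dd, "fitted_shape.csv"))
    for (nm in names(seg$masks))
      png::writePNG(seg$masks[[nm]] + 0, file.path(dd, paste0("mask_", nm, ".png")))
    png::writePNG(seg$label_map / 255, file.path(dd, "label_map.png"))
  }
  seg
}

# structures whose CSAs enter the longitudinal analysis
CSA_STRUCTURES <- c("scf", "imf", "quadriceps", "hamstrings", "adductors",
                    "sartorius")

# per-structure CSAs (cm^2) of a segmentation result or truth label map
csa_of <- function(label_map, spacing) {
  a <- labelmap_areas(label_map, spacing)
  stats::setNames(a$cm2, a$structure)[CSA_STRUCTURES]
}

#' Longitudinal sensitivity experiment
#'
#' Segments paired baseline and follow-up phantoms, computes per-subject
#' percent CSA change per structure and summarizes them as change statistics
#' (mean, SD, SRM, paired t). Truth changes from the truth label maps are
#' reported alongside for recovery checks. Initialization uses the
#' truth-shape-derived pose with the configured perturbation.
#'
#' @param baseline,followup Paired `phantom_dataset`s (same subjects).
#' @param model List with `model` and `profiles`.
#' @param config A [pipeline_config()].
#' @return List with `stats` (data.frame structure / n / mean_change_pct /
#'   sd_change_pct / srm / t_stat / p / truth_mean_change_pct), `changes`
#'   (n x structure matrix, measured %), `truth_changes` (same, from truth
#'   labels).
#' @export
run_longitudinal_experiment <- function(baseline, followup, model,
                                        config = pipeline_config()) {
  n <- length(baseline$subjects)
  if (n != length(followup$subjects))
    stop_thighseg("baseline and follow-up datasets must be paired")
  measured <- truth <- matrix(0, n, length(CSA_STRUCTURES),
                              dimnames = list(NULL, CSA_STRUCTURES))
  for (i in seq_len(n)) {
    sb <- baseline$subjects[[i]]; sf <- followup$subjects[[i]]
    init_b <- init_pose_from_shape(model$model, sb$shape)
    init_f <- init_pose_from_shape(model$model, sf$shape)
    seg_b <- segment_thigh(sb$image, model, init_b, config)
    seg_f <- segment_thigh(sf$image, model, init_f, config)
    sp <- sb$image$spacing
    mb <- csa_of(seg_b$label_map, sp); mf <- csa_of(seg_f$label_map, sp)
    tb <- csa_of(sb$labels, sp); tf <- csa_of(sf$labels, sp)
    measured[i, ] <- 100 * (mf - mb) / mb
    truth[i, ] <- 100 * (tf - tb) / tb
  }
  stats <- do.call(rbind, lapply(CSA_STRUCTURES, function(cmp) {
    cs <- srm_stats(measured[, cmp])
    data.frame(structure = cmp, n = n,
               mean_change_pct = cs$mean_change,
               sd_change_pct = cs$sd_change, srm = cs$srm,
               t_stat = cs$t_stat, p = cs$p_two_sided,
               truth_mean_change_pct = mean(truth[, cmp]),
               stringsAsFactors = FALSE)
  }))
  list(stats = stats, changes = measured, truth_changes = truth)
}
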