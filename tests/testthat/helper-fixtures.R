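# Shared, lazily built and memoized fixtures. All sizes are scaled-down
# analogues of the study conditions (full-scale 256 px / 0.98 mm grid for
# accuracy checks, 128 px grid with 24 outline points per component for the
# repeated-training experiments); seeds are fixed constants.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# 60-subject full-scale cohort: training pool + held-out fits
cohort_256 <- function() fixture("cohort_256", function() {
  generate_cohort(60, seed = 101, grid = 256)
})

preproc_256 <- function() fixture("preproc_256", function() {
  lapply(cohort_256()$subjects,
         function(s) preprocess_image(s$image)$fitted$pixels)
})

# model trained on the first 40 full-scale subjects
model_256 <- function() fixture("model_256", function() {
  thighseg:::train_shape_model(cohort_256()$subjects[1:40],
                               preproc_256()[1:40])
})

# 20-subject experiment cohort at 128 px (cross-validation, determinism)
cohort_128 <- function() fixture("cohort_128", function() {
  generate_cohort(20, seed = 202, grid = 128, points_per_component = 24)
})

model_128 <- function() fixture("model_128", function() {
  pre <- lapply(cohort_128()$subjects,
                function(s) preprocess_image(s$image)$fitted$pixels)
  thighseg:::train_shape_model(cohort_128()$subjects, pre)
})

# model for the longitudinal experiments: its training pool carries generic
# per-structure size variability (zero-mean, 10% SD area scalings) so the
# shape space spans tissue-proportion differences, as a population training
# set would; nearly all variance is retained so these low-variance modes
# survive the PCA cut
model_128_long <- function() fixture("model_128_long", function() {
  vary <- list(
    mean = c(scf = 0, imf = 0, quadriceps = 0, hamstrings = 0,
             adductors = 0, sartorius = 0),
    sd = c(scf = 10, imf = 10, quadriceps = 10, hamstrings = 10,
           adductors = 10, sartorius = 10))
  tr <- generate_cohort(20, seed = 203, grid = 128, points_per_component = 24,
                        longitudinal = vary)
  subs <- c(tr$baseline$subjects, tr$followup$subjects)
  pre <- lapply(subs, function(s) preprocess_image(s$image)$fitted$pixels)
  thighseg:::train_shape_model(subs, pre, variance_retained = 0.999)
})

# 60-subject pool + 8-subject test set at 128 px for the learning curve
pool_128 <- function() fixture("pool_128", function() {
  generate_cohort(60, seed = 303, grid = 128, points_per_component = 24)
})

test_128 <- function() fixture("test_128", function() {
  generate_cohort(8, seed = 304, grid = 128, points_per_component = 24)
})

# bright disk on dark background with an analytic boundary
disk_image <- function(n = 96, r = 25, cx = (n - 1) / 2, cy = (n - 1) / 2) {
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), times = n), n)
  img <- 0.1 + 0.8 * ((xs - cx)^2 + (ys - cy)^2 <= r^2)
  grayscale_image(img, c(1, 1), id = "disk")
}

circle_contour <- function(n, r, cx, cy) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
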