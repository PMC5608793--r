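# synthetic thigh phantom generator

test_that("zero variation returns the canonical template exactly", {
  g0 <- sample_anatomy(seed = 1, b = c(0, 0, 0, 0))
  tmpl <- thighseg:::phantom_template(256, 40)
  for (nm in names(tmpl$outlines))
    expect_equal(g0$outlines[[nm]], tmpl$outlines[[nm]])
  expect_equal(g0$adductor, tmpl$adductor)
})

test_that("anatomy sampling is deterministic and respects the 3-SD gate", {
  a <- sample_anatomy(seed = 5)
  b <- sample_anatomy(seed = 5)
  expect_identical(a$outlines, b$outlines)
  expect_identical(a$vessels, b$vessels)
  expect_error(sample_anatomy(seed = 1, b = c(4, 0, 0, 0)), "3 SD")
})

test_that("sampled geometries satisfy the nesting invariants", {
  for (seed in 1:15) {
    g <- sample_anatomy(seed = seed, grid = 128, points_per_component = 24)
    expect_true(isTRUE(thighseg:::check_anatomy(g)))
  }
})

test_that("sampled mode amplitudes are unbiased", {
  bs <- withr::with_seed(99, t(replicate(1000, sample_anatomy(
    grid = 128, points_per_component = 24)$b)))
  # per-mode mean within 0.1 SD of zero (SE of the mean ~ 0.032)
  expect_true(all(abs(colMeans(bs)) < 0.1))
  expect_true(all(abs(apply(bs, 2, sd) - 1) < 0.12))
})

test_that("noiseless rendering is piecewise constant at the class means", {
  g <- sample_anatomy(seed = 2, grid = 128, points_per_component = 24)
  quiet <- intensity_model(fat = c(0.8, 0), muscle = c(0.35, 0),
                           cortex = c(0.1, 0), medulla = c(0.75, 0),
                           background = c(0.05, 0), noise_sd = 0)
  r <- render_image(g, quiet, seed = 1)
  for (cls in list(c("scf", 0.8), c("imf", 0.8), c("quadriceps", 0.35),
                   c("femur_cortex", 0.1), c("medulla", 0.75))) {
    sel <- r$labels == LABEL_CODES[[cls[1]]]
    expect_true(all(r$image$pixels[sel] == as.numeric(cls[2])))
  }
})

test_that("default rendering reproduces class means within 0.01", {
  g <- sample_anatomy(seed = 3)
  r <- render_image(g, intensity_model(), seed = 7)
  expect_lt(abs(mean(r$image$pixels[r$labels == 1]) - 0.80), 0.01)
  expect_lt(abs(mean(r$image$pixels[r$labels == 3]) - 0.35), 0.01)
  expect_lt(abs(mean(r$image$pixels[r$labels == 7]) - 0.10), 0.01)
})

test_that("truth label maps partition the thigh", {
  g <- sample_anatomy(seed = 4, grid = 128, points_per_component = 24)
  r <- render_image(g, seed = 1)
  thigh_fill <- fill_polygon(g$outlines$thigh, 128, 128)
  expect_true(all(r$labels[thigh_fill == 1] > 0))
  expect_true(all(r$labels[thigh_fill == 0] == 0))
  # vessels exist and each stays below the connected-size threshold
  expect_gte(nrow(g$vessels), 2)
  expect_lte(nrow(g$vessels), 6)
  vess <- (r$labels == LABEL_CODES[["other"]]) + 0L
  if (sum(vess) > 0) {
    lab <- label_components(vess)
    expect_true(all(tabulate(lab[lab > 0]) < 70 * (128 / 256)^2 + 70))
  }
})

test_that("longitudinal change hits requested areas on rasterized truth", {
  g <- sample_anatomy(seed = 6)
  # identity: zero targets leave the geometry unchanged
  expect_identical(apply_longitudinal_change(g, c(quadriceps = 0))$outlines$quadriceps,
                   g$outlines$quadriceps, tolerance = 1e-12)

  area_px <- function(geom, code) {
    r <- render_image(geom, intensity_model(noise_sd = 0), seed = 1)
    sum(r$labels == code)
  }
  g2 <- apply_longitudinal_change(g, c(quadriceps = 2.7))
  ch <- 100 * (area_px(g2, 3) / area_px(g, 3) - 1)
  expect_gte(ch, 2.2); expect_lte(ch, 3.2)

  # SCF reduction averaged over phantoms lands within half a point
  achieved <- vapply(1:20, function(i) {
    gi <- sample_anatomy(seed = 100 + i)
    gj <- apply_longitudinal_change(gi, c(scf = -6.0))
    100 * (area_px(gj, 1) / area_px(gi, 1) - 1)
  }, numeric(1))
  expect_lt(abs(mean(achieved) - (-6.0)), 0.5)
})

test_that("cohort generation is bit-reproducible and shapes train a PDM", {
  d1 <- generate_cohort(5, seed = 11, grid = 128, points_per_component = 24)
  d2 <- generate_cohort(5, seed = 11, grid = 128, points_per_component = 24)
  expect_identical(d1$subjects[[3]]$image$pixels, d2$subjects[[3]]$image$pixels)
  expect_identical(d1$subjects[[3]]$labels, d2$subjects[[3]]$labels)
  expect_identical(d1$subjects[[3]]$shape$points, d2$subjects[[3]]$shape$points)

  # a cohort off the 4-mode generator concentrates variance in 4 modes
  ds <- pool_128()
  al <- align_shapes(lapply(ds$subjects, `[[`, "shape"))
  pdm <- train_pdm(al$aligned, variance_retained = 1)
  expect_gte(sum(pdm$eigenvalues[1:4]) / sum(pdm$eigenvalues), 0.95)
})

test_that("longitudinal cohorts draw changes from the configured law", {
  lg <- list(mean = c(scf = -6.0), sd = c(scf = 9.8))
  dd <- generate_cohort(30, seed = 21, grid = 128, points_per_component = 24,
                        longitudinal = lg)
  expect_length(dd$baseline$subjects, 30)
  expect_length(dd$followup$subjects, 30)
  drawn <- dd$true_changes[, "scf"]
  expect_lt(abs(mean(drawn) - (-6.0)), 2 * 9.8 / sqrt(30))
})

test_that("phantom datasets write to disk with manifest and shapes", {
  ds <- generate_cohort(2, seed = 31, grid = 128, points_per_component = 24)
  dir <- tempfile("phantoms")
  write_phantom_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "phantom_001.tif")))
  sh <- read.csv(file.path(dir, "phantom_001_shape.csv"))
  expect_equal(nrow(sh), nrow(ds$subjects[[1]]$shape$points))
  img <- load_image(file.path(dir, "phantom_001.tif"), spacing = c(1.96, 1.96))
  expect_equal(dim(img$pixels), c(128, 128))
})
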