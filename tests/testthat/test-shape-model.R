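# point distribution model: Procrustes alignment, PCA, profiles, ASM search

make_test_shape <- function(jitter = 0, seed = NULL) {
  build <- function() {
    pts <- rbind(circle_contour(12, 10, 20, 20), circle_contour(8, 4, 20, 20))
    if (jitter > 0) pts <- pts + matrix(rnorm(length(pts), 0, jitter), ncol = 2)
    thigh_shape(pts, rep(c("outer", "inner"), c(12, 8)))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

test_that("Procrustes alignment undoes similarity transforms exactly", {
  s1 <- make_test_shape()
  p <- pose(5, -3, 2, 30 * pi / 180)
  s2 <- thigh_shape(apply_pose(s1$points, p), s1$component)
  al <- align_shapes(list(s1, s2))
  rss <- sum((al$aligned[[1]]$points - al$aligned[[2]]$points)^2)
  expect_lt(rss, 1e-10)
  # mean is centered with unit centroid size
  expect_equal(colMeans(al$mean_shape$points), c(0, 0), tolerance = 1e-8)
  expect_equal(sum(al$mean_shape$points^2), 1, tolerance = 1e-8)
})

test_that("alignment of an already-aligned set is a fixed point", {
  shapes <- lapply(1:4, function(i) make_test_shape(jitter = 0.3, seed = i))
  al1 <- align_shapes(shapes)
  al2 <- align_shapes(al1$aligned)
  for (tf in al2$transforms) {
    expect_lt(abs(tf$tx), 1e-6)
    expect_lt(abs(tf$ty), 1e-6)
    expect_lt(abs(tf$theta), 1e-6)
    expect_lt(abs(tf$s - 1), 1e-6)
  }
})

test_that("the mean of similarity-perturbed noisy copies recovers the template", {
  template <- make_test_shape()
  shapes <- withr::with_seed(42, lapply(1:5, function(i) {
    p <- pose(runif(1, -10, 10), runif(1, -10, 10),
              runif(1, 0.7, 1.4), runif(1, -0.5, 0.5))
    thigh_shape(apply_pose(template$points, p) +
                  matrix(rnorm(40, 0, 0.01), ncol = 2), template$component)
  }))
  al <- align_shapes(shapes)
  # compare in the template frame (undo the similarity between mean and template)
  tf <- thighseg:::fit_similarity(al$mean_shape$points, template$points)
  back <- apply_pose(al$mean_shape$points, tf)
  expect_lt(sqrt(mean((back - template$points)^2)), 0.05)
})

test_that("PCA training: degenerate, generative-recovery and completeness cases", {
  # identical shapes: no variance, zero modes, mean reproduces the input
  same <- replicate(10, make_test_shape(), simplify = FALSE)
  al <- align_shapes(same)
  pdm0 <- train_pdm(al$aligned)
  expect_equal(length(pdm0$eigenvalues), 0)
  expect_equal(thighseg:::pdm_instance(pdm0), al$aligned[[1]]$points,
               tolerance = 1e-8)

  # known 2-mode linear generator (modes orthogonal to the similarity group:
  # an anisotropic stretch and an inner-outline rescaling)
  template <- make_test_shape()
  P <- nrow(template$points)
  ctr <- colMeans(template$points)
  d1 <- cbind((template$points[, 1] - ctr[1]) * 0.05, rep(0, P))
  d2 <- sweep(template$points, 2, ctr) * 0.02
  d2[1:12, ] <- 0  # inner component only
  shapes <- withr::with_seed(7, lapply(1:40, function(i) {
    b <- rnorm(2)
    thigh_shape(template$points + b[1] * d1 + b[2] * d2 +
                  matrix(rnorm(2 * P, 0, 0.001), ncol = 2),
                template$component)
  }))
  alg <- align_shapes(shapes)
  pdm <- train_pdm(alg$aligned, variance_retained = 1)
  expect_gte(sum(pdm$eigenvalues[1:2]) / sum(pdm$eigenvalues), 0.99)

  # full-mode reconstruction of a training shape is exact
  x <- thighseg:::shape_vector(alg$aligned[[3]])
  b <- drop(crossprod(pdm$modes, x - pdm$mean))
  expect_lt(max(abs(pdm$mean + pdm$modes %*% b - x)), 1e-6)

  # modes are orthonormal
  G <- crossprod(pdm$modes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
})

test_that("profile model finds step edges and degenerates to the ridge", {
  img <- disk_image(n = 64, r = 15, cx = 31, cy = 31)
  sh <- thigh_shape(circle_contour(24, 15, 31, 31), rep("edge", 24))
  pm <- train_profiles(list(img), list(sh), k = 4)
  # strongest mean derivative response at the central offset for every point
  centered <- apply(abs(pm$means), 1, which.max)
  expect_true(all(centered == 5))

  # constant image: zero profiles, covariance is the ridge only
  cimg <- matrix(0.5, 64, 64)
  pmc <- train_profiles(list(cimg, cimg), list(sh, sh), k = 3)
  expect_true(all(pmc$means == 0))
  expect_equal(pmc$invcov[, , 1], diag(1 / 1e-10, 7), tolerance = 1e-6)
})

test_that("ASM no-op contract and clamp contract hold", {
  ds <- cohort_128()
  tm <- model_128()
  s <- ds$subjects[[1]]
  img <- preprocess_image(s$image)$fitted$pixels
  init <- init_pose_from_shape(tm$model, s$shape)
  fit0 <- fit_asm(tm$model, tm$profiles, img, init, n_iter = 0)
  expect_equal(fit0$shape$points,
               apply_pose(thighseg:::pdm_instance(tm$model), init))
  expect_true(all(fit0$b == 0))

  fit <- fit_asm(tm$model, tm$profiles, img, init, n_iter = 10)
  lim <- 3 * sqrt(tm$model$eigenvalues)
  expect_true(all(abs(fit$b) <= lim + 1e-12))
})

test_that("ASM fit is deterministic and accurate from a perturbed init", {
  ds <- cohort_128()
  tm <- model_128()
  s <- ds$subjects[[3]]
  img <- preprocess_image(s$image)$fitted$pixels
  init <- perturb_pose(init_pose_from_shape(tm$model, s$shape),
                       dx = 4, dy = -4, dtheta = 4 * pi / 180, dscale = 0.04)
  f1 <- fit_asm(tm$model, tm$profiles, img, init)
  f2 <- fit_asm(tm$model, tm$profiles, img, init)
  expect_identical(f1$shape$points, f2$shape$points)

  d <- sqrt(rowSums((f1$shape$points - s$shape$points)^2))
  expect_lt(mean(d), 2)
})

test_that("shape-to-mask conversion matches the oracle and the cortex identity", {
  sq <- cbind(c(3, 13, 13, 3), c(3, 3, 13, 13))
  tri <- cbind(c(0, 0, 4), c(0, 4, 0))
  sh <- thigh_shape(rbind(sq, tri), rep(c("sq", "tri"), c(4, 3)))
  masks <- shape_to_masks(sh, 32, 32)
  expect_equal(sum(masks$sq), 100)
  expect_equal(masks$sq, oracle_fill_polygon(sq, 32, 32))
  expect_equal(masks$tri, oracle_fill_polygon(tri, 32, 32))

  geom <- sample_anatomy(b = c(0, 0, 0, 0), grid = 128,
                         points_per_component = 24)
  masks <- shape_to_masks(anatomy_shape(geom), 128, 128)
  expect_equal(sum(masks$femur_cortex),
               sum(masks$femur) - sum(masks$medulla))
  expect_true(all(masks$medulla + masks$femur_cortex <= masks$femur))
})

test_that("shapes round-trip through CSV", {
  sh <- make_test_shape(jitter = 0.2, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_shape_csv(sh, path)
  back <- read_shape_csv(path)
  expect_equal(back$points, sh$points, ignore_attr = TRUE)
  expect_identical(as.character(back$component), as.character(sh$component))
})

test_that("model archives round-trip through disk", {
  tm <- model_128()
  dir <- tempfile("archive")
  save_model_archive(tm$model, tm$profiles, dir)
  back <- load_model_archive(dir)
  expect_equal(back$model$mean, tm$model$mean)
  expect_equal(back$model$modes, tm$model$modes)
  expect_equal(back$model$eigenvalues, tm$model$eigenvalues)
  expect_equal(back$profiles$means, tm$profiles$means)
  expect_equal(back$profiles$invcov, tm$profiles$invcov)
  expect_identical(as.character(back$model$component),
                   as.character(tm$model$component))
})
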