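# SCF hull definition, threshold, residual assignment, label map assembly

test_that("SCF is the thigh minus the fascia hull", {
  disk <- function(r, c0 = 47, n = 96)
    (outer((0:(n - 1) - c0)^2, (0:(n - 1) - c0)^2, `+`) <= r^2) + 0L
  thigh <- disk(30); fascia <- disk(20)
  scf <- derive_scf(thigh, fascia)
  expect_equal(sum(scf), sum(thigh) - sum(fascia))  # convex fascia = own hull
  expect_true(all(scf + fascia <= thigh))

  # fascia = thigh -> empty SCF
  expect_equal(sum(derive_scf(thigh, thigh)), 0)

  # empty fascia -> whole thigh, with a warning
  expect_warning(scf0 <- derive_scf(thigh, thigh * 0L), "empty fascia")
  expect_equal(scf0, thigh)
})

test_that("concave fascia: hull membership matches the supporting-line oracle", {
  n <- 48
  thigh <- (outer((0:(n - 1) - 23)^2, (0:(n - 1) - 23)^2, `+`) <= 20^2) + 0L
  fascia <- (outer((0:(n - 1) - 23)^2, (0:(n - 1) - 23)^2, `+`) <= 14^2) + 0L
  # cut a wedge out of the fascia (concavity)
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), times = n), n)
  wedge <- xs > 23 & abs(ys - 23) < 0.35 * (xs - 23)
  fascia[wedge] <- 0L

  hull <- convex_hull_mask(fascia)
  idx <- which(fascia == 1)
  px <- (idx - 1) %/% n; py <- (idx - 1) %% n
  oracle <- matrix(0L, n, n)
  member <- oracle_hull_membership(px, py, as.vector(xs), as.vector(ys))
  oracle[matrix(c(as.vector(ys)[member] + 1, as.vector(xs)[member] + 1),
                ncol = 2)] <- 1L
  expect_identical(hull, oracle)

  # concavity pixels are inside the hull hence excluded from SCF
  scf <- derive_scf(thigh, fascia)
  concavity <- wedge & (outer((0:(n - 1) - 23)^2, (0:(n - 1) - 23)^2, `+`) <= 13^2)
  expect_true(all(scf[concavity] == 0))
})

test_that("threshold is the class-mean midpoint and scale invariant", {
  img <- matrix(0.5, 64, 64)
  scf <- matrix(0L, 64, 64); scf[1:10, 1:10] <- 1L
  quad <- matrix(0L, 64, 64); quad[30:40, 30:40] <- 1L
  ham <- matrix(0L, 64, 64); ham[50:60, 50:60] <- 1L
  img[scf == 1] <- 0.9; img[quad == 1 | ham == 1] <- 0.3
  ctx <- compute_threshold(img, scf, quad, ham)
  expect_equal(ctx$t, 0.6)

  img2 <- img; img2[scf == 1] <- 0.7
  ctx2 <- compute_threshold(img2, scf, quad, ham)
  expect_equal(ctx2$t, 0.5)

  # equal class means -> t equals that mean
  img3 <- img; img3[scf == 1] <- 0.3
  expect_equal(compute_threshold(img3, scf, quad, ham)$t, 0.3)

  expect_error(compute_threshold(img, scf * 0L, quad, ham), "non-empty")
})

test_that("raw-intensity and normalized images give identical labels", {
  set.seed(21)
  n <- 64
  raw <- matrix(runif(n * n, 0, 1000), n, n)
  fascia <- matrix(0L, n, n); fascia[10:55, 10:55] <- 1L
  scf <- matrix(0L, n, n); scf[2:8, 2:60] <- 1L
  quad <- matrix(0L, n, n); quad[12:20, 12:30] <- 1L
  ham <- matrix(0L, n, n); ham[40:50, 12:30] <- 1L
  raw[scf == 1] <- 800 + rnorm(sum(scf), 0, 20)
  raw[quad == 1 | ham == 1] <- 300 + rnorm(sum(quad) + sum(ham), 0, 20)
  nr1 <- normalize_range(raw)
  assigned <- list(quadriceps = quad, hamstrings = ham,
                   sartorius = matrix(0L, n, n), gracilis = matrix(0L, n, n),
                   femur = matrix(0L, n, n))
  run <- function(img) {
    ctx <- compute_threshold(img, scf, quad, ham)
    assign_residual_pixels(img, assigned, fascia, ctx)
  }
  a <- run(nr1$image)
  b <- run((raw - min(raw)) / (max(raw) - min(raw)))
  expect_identical(a$imf, b$imf)
  expect_identical(a$adductors, b$adductors)
})

test_that("the 70-pixel rule splits adductors from other tissue exactly", {
  n <- 64
  fascia <- matrix(1L, n, n)
  assigned <- list(quadriceps = matrix(0L, n, n), hamstrings = matrix(0L, n, n),
                   sartorius = matrix(0L, n, n), gracilis = matrix(0L, n, n),
                   femur = matrix(0L, n, n))
  ctx <- structure(list(mean_si_scf = 0.8, mean_si_qh = 0.3,
                        pixel_lowest = 0, pixel_highest = 1, t = 0.55),
                   class = "threshold_context")
  img <- matrix(0.8, n, n)  # fat background

  blob_img <- function(npix) {
    m <- img
    cols <- ceiling(npix / 8)
    filled <- 0
    for (cc in seq_len(cols)) {
      take <- min(8, npix - filled)
      m[10 + seq_len(take) - 1, 10 + cc - 1] <- 0.3
      filled <- filled + take
    }
    m
  }
  res71 <- assign_residual_pixels(blob_img(71), assigned, fascia, ctx)
  expect_equal(sum(res71$adductors), 71)
  expect_equal(sum(res71$other), 0)

  res70 <- assign_residual_pixels(blob_img(70), assigned, fascia, ctx)
  expect_equal(sum(res70$adductors), 0)
  expect_equal(sum(res70$other), 70)
})

test_that("checkerboard residual agrees with the flood-fill oracle", {
  n <- 16
  fascia <- matrix(1L, n, n)
  assigned <- list(quadriceps = matrix(0L, n, n), hamstrings = matrix(0L, n, n),
                   sartorius = matrix(0L, n, n), gracilis = matrix(0L, n, n),
                   femur = matrix(0L, n, n))
  ctx <- structure(list(mean_si_scf = 0.8, mean_si_qh = 0.3,
                        pixel_lowest = 0, pixel_highest = 1, t = 0.55),
                   class = "threshold_context")
  img <- matrix(0.8, n, n)
  img[(row(img) + col(img)) %% 2 == 0] <- 0.3   # muscle-like checkerboard
  res <- assign_residual_pixels(img, assigned, fascia, ctx)
  muscle_mask <- (img < 0.55) + 0L
  orc <- oracle_label_components(muscle_mask)
  expect_equal(max(orc), 1L)  # diagonally connected into one component
  npix <- sum(muscle_mask)
  if (npix > 70) {
    expect_equal(res$adductors, muscle_mask)
  } else {
    expect_equal(res$other, muscle_mask)
  }
  expect_equal(res$imf, 1L - muscle_mask)
})

test_that("literal threshold polarity reproduces the printed inequality", {
  n <- 64
  fascia <- matrix(1L, n, n)
  assigned <- list(quadriceps = matrix(0L, n, n), hamstrings = matrix(0L, n, n),
                   sartorius = matrix(0L, n, n), gracilis = matrix(0L, n, n),
                   femur = matrix(0L, n, n))
  ctx <- structure(list(mean_si_scf = 0.8, mean_si_qh = 0.3,
                        pixel_lowest = 0, pixel_highest = 1, t = 0.55),
                   class = "threshold_context")
  img <- matrix(0.8, n, n); img[1:8, 1:8] <- 0.3
  lit <- assign_residual_pixels(img, assigned, fascia, ctx,
                                literal_threshold = TRUE)
  # verbatim rule: >= t is the "adductor" pool, < t is IMF
  expect_equal(sum(lit$imf), 64)
  expect_equal(sum(lit$adductors), n * n - 64)
})

test_that("label map assembly applies precedence and area conversion", {
  n <- 64
  zero <- matrix(0L, n, n)
  quad <- zero; quad[10:19, 10:19] <- 1L
  imf <- zero; imf[15:24, 15:24] <- 1L       # overlaps quadriceps by 5 x 5
  masks <- list(scf = zero, quadriceps = quad, hamstrings = zero,
                sartorius = zero, femur_cortex = zero, medulla = zero)
  seg <- assemble_labelmap(masks, imf, zero, zero, spacing = c(0.98, 0.98))
  expect_equal(seg$conflicts, 25)
  expect_equal(sum(seg$label_map == LABEL_CODES[["quadriceps"]]), 100)
  expect_equal(sum(seg$label_map == LABEL_CODES[["imf"]]), 75)
  a <- seg$areas
  expect_equal(a$cm2[a$structure == "quadriceps"], 100 * 0.98^2 / 100)
  # disjoint masks: total labeled = sum of parts
  expect_equal(sum(seg$label_map > 0), 175)
})
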