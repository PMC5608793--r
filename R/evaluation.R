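# Agreement and sensitivity-to-change statistics, twofold cross-validation
# and the training-set-size learning curve.

#' Dice similarity coefficient
#'
#' `DSC = 2|M intersect S| / (|M| + |S|)` between two binary masks on the
#' same grid. Symmetric; undefined (error) when both masks are empty.
#'
#' @param M,S 0/1 matrices of identical size.
#' @return Similarity in `[0, 1]`.
#' @export
dice <- function(M, S) {
  stopifnot(all(dim(M) == dim(S)))
  nm <- sum(M != 0); ns <- sum(S != 0)
  if (nm + ns == 0) stop_thighseg("Dice undefined for two empty masks")
  2 * sum(M != 0 & S != 0) / (nm + ns)
}

#' Bland-Altman agreement analysis
#'
#' Differences are semi-automated minus manual; limits of agreement are the
#' mean difference +/- 1.96 sample SD (n - 1).
#'
#' @param manual,semi Numeric vectors of paired measurements (n >= 2), or a
#'   two-column matrix/data.frame in `manual`.
#' @return Object of class `agreement_stats`: `n`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`.
#' @export
bland_altman <- function(manual, semi = NULL) {
  if (is.null(semi)) {
    manual <- as.matrix(manual)
    semi <- manual[, 2]; manual <- manual[, 1]
  }
  stopifnot(length(manual) == length(semi))
  n <- length(manual)
  if (n < 2) stop_thighseg("need at least 2 pairs")
  d <- semi - manual
  m <- mean(d); s <- stats::sd(d)
  structure(list(n = n, mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s),
            class = "agreement_stats")
}

#' Standardized response mean and paired t test of changes
#'
#' `SRM = mean / SD` of the changes (sample SD); the paired t statistic is
#' `mean / (SD / sqrt(n))`, so `SRM * sqrt(n) = t` exactly. The p value is
#' two-sided from the t distribution with `n - 1` df.
#'
#' @param changes Numeric vector of per-subject changes (n >= 2), typically
#'   percent.
#' @return Object of class `change_stats`: `n`, `mean_change`, `sd_change`,
#'   `srm`, `t_stat`, `p_two_sided`, `df`.
#' @export
srm_stats <- function(changes) {
  n <- length(changes)
  if (n < 2) stop_thighseg("need at least 2 changes")
  m <- mean(changes); s <- stats::sd(changes)
  if (s == 0) stop_thighseg("SRM undefined: zero SD of changes")
  t <- (m / s) * sqrt(n)  # SRM * sqrt(n), the paired t statistic
  structure(list(n = n, mean_change = m, sd_change = s, srm = m / s,
                 t_stat = t, p_two_sided = 2 * stats::pt(-abs(t), n - 1),
                 df = n - 1),
            class = "change_stats")
}

#' Root-mean-square coefficient of variation (%)
#'
#' Inter-observer precision over duplicate measurements: per pair
#' `SD = |a - b| / sqrt(2)`, `CV_i = SD / mean_i * 100`; the result is the
#' root mean square of the `CV_i`.
#'
#' @param a,b Numeric vectors of duplicate measurements (readers 1 and 2),
#'   or a two-column matrix in `a`. All pair means must be positive.
#' @return RMS CV in percent.
#' @export
rms_cv <- function(a, b = NULL) {
  if (is.null(b)) { a <- as.matrix(a); b <- a[, 2]; a <- a[, 1] }
  stopifnot(length(a) == length(b), length(a) >= 1)
  m <- (a + b) / 2
  if (any(m <= 0)) stop_thighseg("pair means must be positive")
  cv <- (abs(a - b) / sqrt(2)) / m * 100
  sqrt(mean(cv^2))
}

# ---- experiment drivers ------------------------------------------------

# preprocess every subject image once (equalize + 2x2 median + normalize)
preprocess_dataset <- function(dataset) {
  lapply(dataset$subjects, function(s) preprocess_image(s$image)$fitted$pixels)
}

# train PDM + profile model from subjects (truth shapes + preprocessed imgs)
train_shape_model <- function(subjects, fitted_imgs, variance_retained = 0.98,
                              k = 6) {
  shapes <- lapply(subjects, `[[`, "shape")
  al <- align_shapes(shapes)
  model <- train_pdm(al$aligned, variance_retained)
  profiles <- train_profiles(fitted_imgs, shapes, k)
  list(model = model, profiles = profiles)
}

# ASM-only fit of one subject; returns per-structure DSC vs truth shape
fit_and_score <- function(tm, fitted_img, subject, n_iter = 30,
                          search_range = 8, perturb = NULL) {
  init <- init_pose_from_shape(tm$model, subject$shape)
  if (!is.null(perturb))
    init <- perturb_pose(init, perturb$dx %||% 0, perturb$dy %||% 0,
                         perturb$dtheta %||% 0, perturb$dscale %||% 0)
  fit <- fit_asm(tm$model, tm$profiles, fitted_img, init,
                 n_iter = n_iter, search_range = search_range)
  nr <- nrow(fitted_img); nc <- ncol(fitted_img)
  mf <- shape_to_masks(fit$shape, nr, nc)
  mt <- shape_to_masks(subject$shape, nr, nc)
  vapply(SHAPE_COMPONENTS, function(cmp) dice(mt[[cmp]], mf[[cmp]]),
         numeric(1))
}

#' Twofold cross-validation of the shape model
#'
#' Repeatedly partitions the dataset into two random disjoint halves, trains
#' the model on one half and fits the other (ASM only, no contour
#' refinement), then swaps — 2 applications per repetition. Per-structure
#' Dice coefficients against the truth shapes are aggregated per
#' application.
#'
#' @param dataset A `phantom_dataset` with at least 10 subjects.
#' @param repetitions Number of repetitions (default 10, i.e. 20
#'   applications).
#' @param seed Integer seed for the partitions.
#' @param n_iter,search_range,variance_retained,k Model/search settings.
#' @return Object of class `cv_report`: `report` (data.frame repetition /
#'   fold / structure / mean_dsc / sd_dsc / n), `per_subject` (data.frame
#'   with one row per fitted subject and structure), `partitions` (list of
#'   index vectors), `seed`.
#' @export
crossvalidate_twofold <- function(dataset, repetitions = 10, seed = 1,
                                  n_iter = 30, search_range = 8,
                                  variance_retained = 0.98, k = 6) {
  n <- length(dataset$subjects)
  if (n < 10) stop_thighseg("cross-validation needs at least 10 subjects")
  fitted_imgs <- preprocess_dataset(dataset)
  rows <- list(); subj_rows <- list(); partitions <- list()
  withr::with_seed(as.integer(seed), {
    for (rep in seq_len(repetitions)) {
      perm <- sample.int(n)
      half <- floor(n / 2)
      folds <- list(perm[seq_len(half)], perm[(half + 1):n])
      partitions[[rep]] <- folds
      for (fold in 1:2) {
        train_idx <- folds[[fold]]
        test_idx <- folds[[3 - fold]]
        tm <- train_shape_model(dataset$subjects[train_idx],
                                fitted_imgs[train_idx],
                                variance_retained, k)
        ds <- t(vapply(test_idx, function(i)
          fit_and_score(tm, fitted_imgs[[i]], dataset$subjects[[i]],
                        n_iter, search_range),
          numeric(length(SHAPE_COMPONENTS))))
        for (cmp in SHAPE_COMPONENTS) {
          rows[[length(rows) + 1]] <- data.frame(
            repetition = rep, fold = fold, structure = cmp,
            mean_dsc = mean(ds[, cmp]), sd_dsc = stats::sd(ds[, cmp]),
            n = length(test_idx), stringsAsFactors = FALSE)
        }
        subj_rows[[length(subj_rows) + 1]] <- data.frame(
          repetition = rep, fold = fold, subject = test_idx,
          ds, stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  })
  structure(list(report = do.call(rbind, rows),
                 per_subject = do.call(rbind, subj_rows),
                 partitions = partitions, seed = as.integer(seed)),
            class = "cv_report")
}

#' Training-set-size learning curve
#'
#' Trains models on increasing random subsets of the pool (in steps of
#' `step`, `randomizations` random draws per size) and fits a fixed held-out
#' test set (ASM only, no contour refinement), recording the mean and
#' min/max across draws of the per-structure test Dice.
#'
#' @param pool `phantom_dataset` used for training draws (>= 2 * step).
#' @param test_set Held-out `phantom_dataset`.
#' @param step Size increment (default 5).
#' @param randomizations Draws per size (default 5).
#' @param seed Integer seed for the draws.
#' @param n_iter,search_range,variance_retained,k Model/search settings.
#' @return data.frame `n_train` / `structure` / `mean_dsc` / `min_dsc` /
#'   `max_dsc` (mean, min and max across draws of the test-set average).
#' @export
learning_curve <- function(pool, test_set, step = 5, randomizations = 5,
                           seed = 1, n_iter = 30, search_range = 8,
                           variance_retained = 0.98, k = 6) {
  n_pool <- length(pool$subjects)
  if (n_pool < 2 * step) stop_thighseg("pool too small for the learning curve")
  pool_imgs <- preprocess_dataset(pool)
  test_imgs <- preprocess_dataset(test_set)
  sizes <- seq(step, n_pool, by = step)
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (sz in sizes) {
      draw_means <- matrix(NA_real_, randomizations, length(SHAPE_COMPONENTS),
                           dimnames = list(NULL, SHAPE_COMPONENTS))
      for (d in seq_len(randomizations)) {
        idx <- sample.int(n_pool, sz)
        tm <- train_shape_model(pool$subjects[idx], pool_imgs[idx],
                                variance_retained, k)
        ds <- t(vapply(seq_along(test_set$subjects), function(i)
          fit_and_score(tm, test_imgs[[i]], test_set$subjects[[i]],
                        n_iter, search_range),
          numeric(length(SHAPE_COMPONENTS))))
        draw_means[d, ] <- colMeans(ds)
      }
      for (cmp in SHAPE_COMPONENTS) {
        rows[[length(rows) + 1]] <- data.frame(
          n_train = sz, structure = cmp,
          mean_dsc = mean(draw_means[, cmp]),
          min_dsc = min(draw_means[, cmp]),
          max_dsc = max(draw_means[, cmp]), stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}
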