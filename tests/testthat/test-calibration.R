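## small deterministic cohort builder: auto_time curves are monotone in the
## threshold; manual time equals the curve at theta* plus optional noise
toy_dataset <- function(n_mice = 16, theta_star = 0.8, noise_sd = 0,
                        seed = 1, thresholds = c(0.4, 0.6, 0.8, 1.0, 1.2)) {
  set.seed(seed)
  base <- runif(n_mice, 120, 260)
  slope <- runif(n_mice, 30, 60)
  rows <- do.call(rbind, lapply(seq_len(n_mice), function(i) {
    data.frame(mouse_id = sprintf("M%02d", i), threshold = thresholds,
               auto_time = base[i] + slope[i] * (thresholds - 0.4))
  }))
  man <- data.frame(
    mouse_id = sprintf("M%02d", seq_len(n_mice)),
    manual_time = base + slope * (theta_star - 0.4) +
      rnorm(n_mice, sd = noise_sd))
  list(scores = rows, manual = man)
}

test_that("mae follows its definition and error contract", {
  expect_equal(mae(c(1, 3), c(2, 5)), 1.5)
  expect_equal(mae(1:5, 1:5), 0)
  set.seed(81)
  a <- runif(100, 0, 360); b <- runif(100, 0, 360)
  expect_equal(mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
  expect_error(mae(1:3, 1:4), "unpaired vectors")
})

test_that("dataset assembly crosses mice with thresholds and rejects unpaired subjects", {
  d <- toy_dataset(16)
  ds <- build_dataset(d$scores, d$manual)
  expect_equal(nrow(ds), 80L)
  expect_equal(length(unique(ds$mouse_id)), 16L)
  expect_true(all(tapply(ds$manual_time, ds$mouse_id,
                         function(x) length(unique(x))) == 1L))

  one <- build_dataset(data.frame(mouse_id = "M1", threshold = 0.8,
                                  auto_time = 100),
                       data.frame(mouse_id = "M1", manual_time = 101))
  expect_equal(nrow(one), 1L)

  expect_error(build_dataset(d$scores, d$manual[-1, ]), "unpaired subject")
})

test_that("animal-level split is leak-free, sized, and deterministic", {
  d <- toy_dataset(16)
  ds <- build_dataset(d$scores, d$manual)
  sp <- split_by_animal(ds, seed = 42)
  expect_equal(length(sp$train_mice), 12L)
  expect_equal(length(sp$test_mice), 4L)
  expect_length(intersect(sp$train_mice, sp$test_mice), 0L)
  sp2 <- split_by_animal(ds, seed = 42)
  expect_identical(sp$train_mice, sp2$train_mice)
  expect_error(split_by_animal(build_dataset(
    d$scores[d$scores$mouse_id %in% sprintf("M%02d", 1:3), ], d$manual)),
    "too few subjects")
})

test_that("no subject leaks across splits or grouped folds over 100 seeds", {
  d <- toy_dataset(16)
  ds <- build_dataset(d$scores, d$manual)
  for (s in 1:100) {
    sp <- split_by_animal(ds, seed = s)
    expect_length(intersect(unique(sp$train$mouse_id),
                            unique(sp$test$mouse_id)), 0L)
    folds <- group_kfold(sp$train$mouse_id, k = 5)
    per_mouse <- tapply(folds, sp$train$mouse_id,
                        function(f) length(unique(f)))
    expect_true(all(per_mouse == 1L))
  }
})

test_that("grouped cross-validation matches a hand-rolled fold loop", {
  d <- toy_dataset(10, noise_sd = 3, seed = 5)
  ds <- build_dataset(d$scores, d$manual)
  spec <- rf_spec(ntree = 50)
  got <- cross_validate(ds, spec)
  folds <- group_kfold(ds$mouse_id, k = 5)
  by_hand <- mean(sapply(1:5, function(f) {
    m <- fit_model(ds[folds != f, ], spec)
    mean(abs(predict(m, ds[folds == f, ]) - ds$manual_time[folds == f]))
  }))
  expect_equal(got, by_hand, tolerance = 1e-9)
  expect_error(cross_validate(build_dataset(
    d$scores[d$scores$mouse_id %in% sprintf("M%02d", 1:4), ], d$manual)),
    "too few groups")
})

test_that("forest fitting is reproducible and near-interpolates duplicated targets", {
  d <- toy_dataset(16, theta_star = 0.8)
  ds <- build_dataset(d$scores, d$manual)
  ds$manual_time <- ds$auto_time     # target == feature everywhere
  m1 <- fit_model(ds)
  m2 <- fit_model(ds)
  expect_identical(predict(m1, ds), predict(m2, ds))
  ## duplicated training points with unanimous targets are reproduced
  dup <- ds[rep(seq_len(nrow(ds)), each = 5), ]
  m3 <- fit_model(dup)
  expect_lt(max(abs(predict(m3, dup) - dup$auto_time)), 1)
  expect_error(fit_model(ds[0, ]), "no training data")
})

test_that("model selection keeps the baseline unless tuning strictly improves", {
  d <- toy_dataset(12, noise_sd = 2, seed = 9)
  ds <- build_dataset(d$scores, d$manual)
  sel <- tune_model(ds, n_draws = 5, seed = 42)
  expect_true(sel$model_choice %in% c("baseline", "tuned"))
  if (sel$model_choice == "baseline") {
    expect_gte(sel$tuned_cv_mae, sel$baseline_cv_mae)
  } else {
    expect_lt(sel$tuned_cv_mae, sel$baseline_cv_mae)
  }
  sel2 <- tune_model(ds, n_draws = 5, seed = 42)
  expect_identical(sel$model_choice, sel2$model_choice)
  expect_equal(sel$cv_mae, sel2$cv_mae)
})

test_that("noise-free GBT recovery is exact to the grid step", {
  d <- toy_dataset(16, theta_star = 0.8, noise_sd = 0)
  ds <- build_dataset(d$scores, d$manual)
  model <- fit_model(ds)
  res <- estimate_global_threshold(model, ds, objective = "auto_vs_manual")
  expect_equal(res$global_best_threshold, 0.8, tolerance = 1e-9)
  expect_true(all(abs(res$individual_thresholds - 0.8) <= 0.001 + 1e-12))
})

test_that("GBT recovery with noisy manual times lands near the generating threshold", {
  d <- toy_dataset(16, theta_star = 0.8, noise_sd = 1, seed = 3)
  calib <- calibrate_threshold(d$scores, d$manual, tune = FALSE)
  expect_lt(abs(calib$global_best_threshold - 0.8), 0.05)
  expect_true(calib$gbt_in_individual_range)
  expect_gte(calib$cv_mae, 0)
  expect_gte(calib$test_mae, 0)
  ## individual thresholds bracket the GBT
  expect_gte(calib$global_best_threshold, min(calib$individual_thresholds))
  expect_lte(calib$global_best_threshold, max(calib$individual_thresholds))
})

test_that("candidate-threshold MAE is U-shaped around the generating threshold", {
  d <- toy_dataset(16, theta_star = 0.8, noise_sd = 1, seed = 13)
  ds <- build_dataset(d$scores, d$manual)
  cand <- sort(unique(ds$threshold))
  maes <- sapply(cand, function(th) {
    sub <- ds[ds$threshold == th, ]
    mae(sub$auto_time, sub$manual_time)
  })
  expect_equal(cand[which.min(maes)], 0.8)
})

test_that("calibration serializes to JSON and back", {
  d <- toy_dataset(8, theta_star = 0.8, noise_sd = 1, seed = 4)
  calib <- calibrate_threshold(d$scores, d$manual, tune = FALSE)
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration(calib, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$gbt, calib$global_best_threshold)
  expect_equal(back$model_choice, calib$model_choice)
})
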