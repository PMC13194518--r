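## Random-Forest calibration of the immobility-detection threshold against
## manual reference scores: animal-level train/test split, grouped 5-fold
## cross-validation, randomized hyperparameter search, and a dense
## threshold-grid scan for the global best threshold (GBT).

#' Mean absolute error
#'
#' @param auto_times,manual_times paired numeric vectors of equal length.
#' @return mean of `|auto - manual|` in the input units (seconds here).
#' @export
mae <- function(auto_times, manual_times) {
  if (length(auto_times) != length(manual_times) ||
      length(auto_times) == 0L) {
    stop("unpaired vectors", call. = FALSE)
  }
  mean(abs(auto_times - manual_times))
}

#' Assemble the calibration dataset
#'
#' Full cross of mice and candidate thresholds: one row per (mouse,
#' threshold) holding the automated immobility time at that threshold and
#' the mouse's (threshold-independent) manual reference time. No rows are
#' deleted or imputed.
#'
#' @param cohort_scores data frame with columns `mouse_id`, `threshold`,
#'   `auto_time` (one row per mouse x threshold).
#' @param manual data frame with columns `mouse_id`, `manual_time`.
#'
#' @return A data frame of class `calibration_dataset` with columns
#'   `mouse_id`, `threshold`, `auto_time`, `manual_time`, ordered by mouse
#'   then threshold.
#' @export
build_dataset <- function(cohort_scores, manual) {
  stopifnot(all(c("mouse_id", "threshold", "auto_time") %in%
                  names(cohort_scores)),
            all(c("mouse_id", "manual_time") %in% names(manual)))
  mice <- sort(unique(as.character(cohort_scores$mouse_id)))
  if (!all(mice %in% as.character(manual$mouse_id))) {
    stop("unpaired subject", call. = FALSE)
  }
  thr_sets <- tapply(cohort_scores$threshold, cohort_scores$mouse_id,
                     function(x) paste(sort(x), collapse = ","))
  if (length(unique(thr_sets)) != 1L) {
    stop("every mouse must be scored at the same threshold set",
         call. = FALSE)
  }
  df <- cohort_scores[order(cohort_scores$mouse_id,
                            cohort_scores$threshold), , drop = FALSE]
  df$mouse_id <- as.character(df$mouse_id)
  df$manual_time <- manual$manual_time[match(df$mouse_id,
                                             as.character(manual$mouse_id))]
  if (any(df$auto_time < 0 | df$auto_time > 360 + 1e-9) ||
      any(df$manual_time < 0 | df$manual_time > 360 + 1e-9)) {
    stop("immobility times must lie in [0, 360] s", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("calibration_dataset", "data.frame")
  df
}

#' Animal-level train/test split
#'
#' All rows of a given mouse are confined to a single partition, preventing
#' leakage between train and test.
#'
#' @param dataset a [build_dataset()] result.
#' @param train_frac fraction of mice assigned to training (default 0.75).
#' @param seed RNG seed for the split (default 42).
#'
#' @return list with elements `train` and `test` (both
#'   `calibration_dataset`s) and `train_mice` / `test_mice`.
#' @export
split_by_animal <- function(dataset, train_frac = 0.75, seed = 42) {
  mice <- sort(unique(dataset$mouse_id))
  if (length(mice) < 4L) stop("too few subjects to split", call. = FALSE)
  n_train <- round(train_frac * length(mice))
  train_mice <- withr_seed(seed, sample(mice, n_train))
  test_mice <- setdiff(mice, train_mice)
  list(train = dataset[dataset$mouse_id %in% train_mice, , drop = FALSE],
       test = dataset[dataset$mouse_id %in% test_mice, , drop = FALSE],
       train_mice = sort(train_mice), test_mice = sort(test_mice))
}

## evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Deterministic grouped K-fold assignment
#'
#' Groups (mice) are assigned whole to folds so that no group spans folds;
#' larger groups are placed first into the currently smallest fold, which
#' balances fold sizes.
#'
#' @param ids vector of group ids, one per row.
#' @param k number of folds.
#' @return integer fold index per row.
#' @export
group_kfold <- function(ids, k = 5) {
  ids <- as.character(ids)
  counts <- table(ids)
  if (length(counts) < k) {
    stop("too few groups for 5-fold grouping", call. = FALSE)
  }
  ord <- order(-as.integer(counts), names(counts))
  fold_of <- character(0)
  fold_sizes <- integer(k)
  fold_map <- setNames(integer(length(counts)), names(counts)[ord])
  for (g in names(counts)[ord]) {
    f <- which.min(fold_sizes)
    fold_map[g] <- f
    fold_sizes[f] <- fold_sizes[f] + counts[[g]]
  }
  unname(fold_map[ids])
}

#' Random-Forest model specification
#'
#' The baseline specification is a 200-tree forest with fully grown trees
#' (terminal nodes of size 1) considering both features at every split --
#' the defaults of the scikit-learn-style regressor this calibration
#' mirrors. The tuning search draws from `ntree` 100--600, `maxnodes`
#' unlimited or in {16, 32, 64, 128, 256}, `nodesize` 1--8 and `mtry`
#' 1--2.
#'
#' @param ntree number of trees.
#' @param mtry variables tried at each split (`NULL` = all features).
#' @param nodesize minimum size of terminal nodes.
#' @param maxnodes maximum number of terminal nodes (`NULL` = unlimited).
#' @param seed RNG seed used when fitting.
#' @return list of class `rf_spec`.
#' @export
rf_spec <- function(ntree = 200, mtry = NULL, nodesize = 1,
                    maxnodes = NULL, seed = 42) {
  structure(list(ntree = ntree, mtry = mtry, nodesize = nodesize,
                 maxnodes = maxnodes, seed = seed),
            class = "rf_spec")
}

#' Fit the threshold-response Random Forest
#'
#' Learns the mapping `(threshold, auto_time) -> manual_time`. Fitting is
#' reproducible under the specification's seed.
#'
#' @param train a `calibration_dataset` (training partition).
#' @param spec an [rf_spec()].
#' @return An object of class `threshold_model` wrapping the fitted forest.
#' @export
fit_model <- function(train, spec = rf_spec()) {
  if (is.null(train) || nrow(train) == 0L) {
    stop("no training data", call. = FALSE)
  }
  args <- list(x = train[, c("threshold", "auto_time")],
               y = train$manual_time, ntree = spec$ntree,
               mtry = if (is.null(spec$mtry)) 2L else spec$mtry,
               nodesize = spec$nodesize)
  if (!is.null(spec$maxnodes)) {
    args$maxnodes <- min(spec$maxnodes, nrow(train))
  }
  ## small cohorts legitimately have few unique manual times; the forest's
  ## "five or fewer unique values" regression warning is noise here
  rf <- withCallingHandlers(
    withr_seed(spec$seed, do.call(randomForest::randomForest, args)),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(rf = rf, spec = spec), class = "threshold_model")
}

#' @export
predict.threshold_model <- function(object, newdata, ...) {
  as.numeric(predict(object$rf,
                     newdata = newdata[, c("threshold", "auto_time")]))
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> random forest, %d trees\n", x$spec$ntree))
  invisible(x)
}

#' Grouped cross-validated MAE of a model specification
#'
#' 5-fold grouped cross-validation (each mouse's rows confined to one
#' fold); returns the fold-mean MAE of predicted vs observed manual times.
#'
#' @param train a `calibration_dataset`.
#' @param spec an [rf_spec()].
#' @param k number of folds (default 5).
#' @return mean MAE over folds, in seconds.
#' @export
cross_validate <- function(train, spec = rf_spec(), k = 5) {
  folds <- group_kfold(train$mouse_id, k = k)
  fold_mae <- vapply(seq_len(k), function(f) {
    fit <- fit_model(train[folds != f, , drop = FALSE], spec)
    pred <- predict(fit, train[folds == f, , drop = FALSE])
    mae(pred, train$manual_time[folds == f])
  }, numeric(1))
  mean(fold_mae)
}

#' Randomized hyperparameter search with grouped cross-validation
#'
#' Draws `n_draws` specifications from predefined ranges, scores each with
#' the same grouped cross-validation as the baseline, and keeps the
#' baseline unless a tuned specification strictly improves the CV MAE.
#'
#' @param train a `calibration_dataset`.
#' @param baseline_spec the baseline [rf_spec()].
#' @param n_draws number of random draws (default 25).
#' @param seed RNG seed for the search (default 42).
#' @param k folds for the grouped cross-validation.
#'
#' @return list with `model_choice` (`"baseline"` or `"tuned"`), `spec`
#'   (the selected specification), `cv_mae` (its CV MAE),
#'   `baseline_cv_mae`, `tuned_cv_mae`.
#' @export
tune_model <- function(train, baseline_spec = rf_spec(), n_draws = 25,
                       seed = 42, k = 5) {
  baseline_cv <- cross_validate(train, baseline_spec, k = k)
  draws <- withr_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      rf_spec(
        ntree = sample(seq(100, 600, by = 50), 1),
        maxnodes = sample(c(list(NULL), as.list(c(16L, 32L, 64L, 128L,
                                                  256L))), 1)[[1]],
        nodesize = sample(1:8, 1),
        mtry = sample(1:2, 1),
        seed = baseline_spec$seed)
    })
  })
  tuned_cv <- vapply(draws, function(sp) cross_validate(train, sp, k = k),
                     numeric(1))
  best <- which.min(tuned_cv)
  if (tuned_cv[best] < baseline_cv) {
    list(model_choice = "tuned", spec = draws[[best]],
         cv_mae = tuned_cv[best], baseline_cv_mae = baseline_cv,
         tuned_cv_mae = tuned_cv[best])
  } else {
    list(model_choice = "baseline", spec = baseline_spec,
         cv_mae = baseline_cv, baseline_cv_mae = baseline_cv,
         tuned_cv_mae = tuned_cv[best])
  }
}

#' Estimate the global best threshold (GBT)
#'
#' Scans a dense threshold grid over the candidate range. For each grid
#' threshold, the per-mouse automated time is obtained either by
#' recomputation from the signal (`auto_fun`) or by monotone piecewise
#' linear interpolation across the candidate thresholds, and the model
#' predicts the manual time from `(threshold, auto_time)`. The GBT
#' minimizes the chosen error objective averaged over mice (smallest
#' threshold on ties). Per-mouse optimal thresholds (the argmin of
#' `|auto(theta) - manual|` for each mouse) are returned for validation,
#' together with a check that the GBT lies within their range.
#'
#' @param model a fitted `threshold_model`.
#' @param dataset the full `calibration_dataset`.
#' @param grid_step threshold grid step in grams (default 0.001).
#' @param objective error objective minimized by the GBT:
#'   `"auto_vs_predicted"` (default) is the mean over mice of
#'   `|auto(theta) - predicted manual(theta)|`; `"auto_vs_manual"` is the
#'   model-free mean of `|auto(theta) - manual|`; `"predicted_vs_manual"`
#'   is the mean of `|predicted manual(theta) - manual|`.
#' @param auto_fun optional `function(mouse_id, thresholds)` returning
#'   recomputed automated times; defaults to interpolation across the
#'   candidate thresholds.
#'
#' @return An object of class `calibration_result` with fields
#'   `global_best_threshold`, `individual_thresholds` (named per mouse),
#'   `gbt_in_individual_range`, `objective`, `grid` (data frame
#'   `threshold`, `error_s`), plus `cv_mae`, `test_mae`, `model_choice`
#'   slots filled by [calibrate_threshold()].
#' @export
estimate_global_threshold <- function(model, dataset, grid_step = 0.001,
                                      objective = c("auto_vs_predicted",
                                                    "auto_vs_manual",
                                                    "predicted_vs_manual"),
                                      auto_fun = NULL) {
  objective <- match.arg(objective)
  cand <- sort(unique(dataset$threshold))
  lo <- min(cand); hi <- max(cand)
  if (!(hi > lo) || grid_step <= 0) {
    stop("degenerate threshold range", call. = FALSE)
  }
  grid <- seq(lo, hi, by = grid_step)
  mice <- sort(unique(dataset$mouse_id))
  manual <- vapply(mice, function(m) {
    dataset$manual_time[dataset$mouse_id == m][1]
  }, numeric(1))
  auto_mat <- vapply(mice, function(m) {
    rows <- dataset[dataset$mouse_id == m, , drop = FALSE]
    rows <- rows[order(rows$threshold), , drop = FALSE]
    if (is.null(auto_fun)) {
      approx(rows$threshold, rows$auto_time, xout = grid)$y
    } else {
      auto_fun(m, grid)
    }
  }, numeric(length(grid)))           # grid x mice
  err_mat <- switch(objective,
    auto_vs_manual = abs(sweep(auto_mat, 2, manual)),
    {
      pred_mat <- vapply(seq_along(mice), function(j) {
        predict(model, data.frame(threshold = grid,
                                  auto_time = auto_mat[, j]))
      }, numeric(length(grid)))
      if (objective == "auto_vs_predicted") abs(auto_mat - pred_mat)
      else abs(sweep(pred_mat, 2, manual))
    })
  obj <- rowMeans(err_mat)
  gbt <- grid[which.min(obj)]
  indiv <- vapply(seq_along(mice), function(j) {
    grid[which.min(abs(auto_mat[, j] - manual[j]))]
  }, numeric(1))
  names(indiv) <- mice
  structure(
    list(global_best_threshold = gbt,
         individual_thresholds = indiv,
         gbt_in_individual_range = gbt >= min(indiv) & gbt <= max(indiv),
         objective = objective,
         grid = data.frame(threshold = grid, error_s = obj),
         cv_mae = NA_real_, test_mae = NA_real_,
         model_choice = NA_character_),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    paste0("<calibration_result> GBT %.3f g (%s objective), individual ",
           "thresholds %.3f-%.3f g\n  model: %s, CV MAE %.2f s, ",
           "test MAE %.2f s\n"),
    x$global_best_threshold, x$objective,
    min(x$individual_thresholds), max(x$individual_thresholds),
    x$model_choice, x$cv_mae, x$test_mae))
  invisible(x)
}

#' Full threshold-calibration workflow
#'
#' Builds the mouse x threshold dataset, performs the animal-level 75/25
#' split, compares the baseline forest against a randomized search under
#' grouped 5-fold cross-validation, fits the selected model on the full
#' training partition, evaluates it once on the held-out mice, and scans
#' the dense grid for the global best threshold.
#'
#' @param cohort_scores,manual as in [build_dataset()].
#' @param train_frac,seed split parameters (see [split_by_animal()]).
#' @param grid_step,objective,auto_fun passed to
#'   [estimate_global_threshold()].
#' @param tune if `FALSE`, skip the randomized search and use the baseline
#'   specification.
#' @param n_draws draws for the randomized search.
#'
#' @return A `calibration_result` (see [estimate_global_threshold()]) with
#'   `cv_mae`, `test_mae`, `model_choice` and the split recorded.
#' @export
calibrate_threshold <- function(cohort_scores, manual, train_frac = 0.75,
                                seed = 42, grid_step = 0.001,
                                objective = "auto_vs_predicted",
                                auto_fun = NULL, tune = TRUE, n_draws = 25) {
  dataset <- build_dataset(cohort_scores, manual)
  split <- split_by_animal(dataset, train_frac = train_frac, seed = seed)
  baseline_spec <- rf_spec(seed = seed)
  if (tune) {
    sel <- tune_model(split$train, baseline_spec, n_draws = n_draws,
                      seed = seed)
  } else {
    sel <- list(model_choice = "baseline", spec = baseline_spec,
                cv_mae = cross_validate(split$train, baseline_spec))
  }
  model <- fit_model(split$train, sel$spec)
  test_mae <- mae(predict(model, split$test), split$test$manual_time)
  res <- estimate_global_threshold(model, dataset, grid_step = grid_step,
                                   objective = objective,
                                   auto_fun = auto_fun)
  res$cv_mae <- sel$cv_mae
  res$test_mae <- test_mae
  res$model_choice <- sel$model_choice
  res$train_mice <- split$train_mice
  res$test_mice <- split$test_mice
  res$seed <- seed
  res
}

#' Serialize a calibration result to JSON
#'
#' @param result a `calibration_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(gbt = result$global_best_threshold,
         individual_thresholds = as.list(result$individual_thresholds),
         gbt_in_individual_range = result$gbt_in_individual_range,
         objective = result$objective,
         cv_mae = result$cv_mae, test_mae = result$test_mae,
         model_choice = result$model_choice, seed = result$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
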