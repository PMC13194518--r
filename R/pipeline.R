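## Batch driver wiring the modules into the full workflow. Each subcommand
## maps to one pipeline stage; failures are isolated per subject so one
## corrupt log never aborts a batch.

#' Score one recording end to end
#'
#' Detects the session start, extracts and filters the observation window,
#' computes the movement envelope, classifies bouts at the detection
#' threshold, and summarizes the behavioral outcome measures.
#'
#' @param trace a [force_trace()].
#' @param threshold detection threshold in grams (default from config,
#'   0.792 g).
#' @param config configuration from [tst_config()].
#' @param start_override optional manual start time (s).
#' @param subject_id subject identifier.
#'
#' @return list with `segmentation`, `window`, `bouts` (`bout_series`),
#'   `summary` (`score_summary`), and `track` (the automated
#'   [annotation_track()] in absolute session time).
#' @export
score_session <- function(trace, threshold = NULL, config = tst_config(),
                          start_override = NULL, subject_id = "s1") {
  if (is.null(threshold)) threshold <- config$score.threshold_g
  det <- detect_session(trace, config = config,
                        start_override = start_override)
  env <- movement_envelope(det$window,
                           span_s = config$score.envelope_span_s)
  bouts <- classify_states(env, threshold, rate = det$window$rate,
                           min_bout_s = config$score.min_bout_s)
  summ <- summarize_bouts(bouts, subject_id = subject_id)
  list(segmentation = det$segmentation, window = det$window,
       bouts = bouts, summary = summ,
       track = as_annotation_track(bouts,
                                   t0 = det$segmentation$refined_start))
}

#' Run a pipeline stage over a batch of inputs
#'
#' Single entry point behind the `tstscore` command-line script. Outputs
#' are deterministic for fixed inputs and seed; per-subject failures are
#' recorded and the remainder of the batch still runs (the returned status
#' is non-zero if any subject failed). The effective configuration is
#' echoed into the output directory as `config_used.yaml`.
#'
#' @param command one of `"simulate"`, `"score"`, `"calibrate"`,
#'   `"evaluate"`, `"photometry"`.
#' @param config configuration list from [tst_config()] /
#'   [load_config()].
#' @param inputs character vector of input files (force logs for `score`;
#'   `evaluate` takes the reference first via `reference`).
#' @param out_dir output directory (created if needed).
#' @param seed run seed (simulation and calibration).
#' @param n cohort size for `simulate`.
#' @param threshold detection threshold for `score` (default from config).
#' @param start_override optional manual start time for `score`.
#' @param reference reference annotation file for `evaluate`.
#' @param manual manual-times CSV (`mouse_id, manual_time`) for
#'   `calibrate`; its companion `inputs` is the scores CSV
#'   (`mouse_id, threshold, auto_time`).
#' @param bouts annotation CSV of scored bouts for `photometry`.
#' @param quiet suppress per-subject log lines.
#'
#' @return invisibly, a list with `status` (0 = all subjects succeeded),
#'   `results`, `errors`.
#' @export
run_batch <- function(command = c("simulate", "score", "calibrate",
                                  "evaluate", "photometry"),
                      config = tst_config(), inputs = character(),
                      out_dir = ".", seed = 1, n = 16, threshold = NULL,
                      start_override = NULL, reference = NULL,
                      manual = NULL, bouts = NULL, quiet = FALSE) {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config_used.yaml"))
  log_line <- function(...) if (!quiet) message(sprintf(...))
  errors <- list()
  results <- list()

  if (command == "simulate") {
    cohort <- simulate_cohort(n = n, seed = seed)
    for (s in cohort) {
      write_force_log(s$session$trace,
                      file.path(out_dir, paste0(s$subject_id, "_log.csv")))
      write_annotation(s$session$truth_bouts,
                       file.path(out_dir,
                                 paste0(s$subject_id, "_truth.csv")),
                       subject = s$subject_id)
      write_annotation(s$manual,
                       file.path(out_dir,
                                 paste0(s$subject_id, "_manual.csv")),
                       subject = s$subject_id)
      log_line("%s: simulated (start %.1f s, immobility %.1f s)",
               s$subject_id, s$session$truth_start_s,
               s$session$truth_total_immobility_s)
    }
    results$cohort <- cohort
  }

  if (command == "score") {
    summaries <- list()
    for (path in inputs) {
      sid <- sub("_log$", "", tools::file_path_sans_ext(basename(path)))
      res <- tryCatch({
        trace <- read_force_log(path)
        sc <- score_session(trace, threshold = threshold, config = config,
                            start_override = start_override,
                            subject_id = sid)
        jsonlite::write_json(
          list(subject = sid,
               refined_start = sc$segmentation$refined_start,
               provisional_start = sc$segmentation$provisional_start,
               baseline = sc$segmentation$baseline,
               threshold = sc$bouts$threshold_used,
               total_immobility = sc$summary$total_immobility,
               latency = sc$summary$latency),
          file.path(out_dir, paste0(sid, "_segmentation.json")),
          auto_unbox = TRUE, digits = NA)
        write_annotation(sc$track,
                         file.path(out_dir, paste0(sid, "_bouts.csv")),
                         subject = sid)
        log_line("%s: start %.3f s, threshold %.3f g, immobility %.1f s, latency %.1f s",
                 sid, sc$segmentation$refined_start,
                 sc$bouts$threshold_used, sc$summary$total_immobility,
                 sc$summary$latency)
        sc
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[sid]] <- conditionMessage(res)
        log_line("%s: FAILED (%s)", sid, conditionMessage(res))
      } else {
        summaries[[sid]] <- res$summary
        results[[sid]] <- res
      }
    }
    if (length(summaries) > 0L) {
      write_score_report(summaries, file.path(out_dir, "score_report.csv"))
    }
  }

  if (command == "calibrate") {
    res <- tryCatch({
      scores <- read.csv(inputs[1], stringsAsFactors = FALSE)
      man <- read.csv(manual, stringsAsFactors = FALSE)
      calib <- calibrate_threshold(
        scores, man, seed = seed,
        grid_step = config$calibration.grid_step_g,
        train_frac = config$calibration.train_frac)
      write_calibration(calib, file.path(out_dir, "calibration.json"))
      log_line("GBT %.3f g (CV MAE %.2f s, test MAE %.2f s, %s model)",
               calib$global_best_threshold, calib$cv_mae, calib$test_mae,
               calib$model_choice)
      calib
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors$calibrate <- conditionMessage(res)
    } else results$calibration <- res
  }

  if (command == "evaluate") {
    res <- tryCatch({
      ref <- read_annotation(reference)
      cands <- lapply(inputs, read_annotation, source = "automated",
                      rate = 80)
      names(cands) <- vapply(inputs, function(p) {
        tools::file_path_sans_ext(basename(p))
      }, character(1))
      ## automated windows are anchored at detected starts, which may sit
      ## up to ~0.5 s from the annotated start
      rep <- compare_methods(ref, cands, span_tol = 0.5)
      write.csv(rep, file.path(out_dir, "agreement_report.csv"),
                row.names = FALSE)
      rep
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors$evaluate <- conditionMessage(res)
    } else results$agreement <- res
  }

  if (command == "photometry") {
    res <- tryCatch({
      ses <- read_photometry(inputs[1])
      bts <- read_annotation(bouts, source = "automated", rate = 80)
      dff <- compute_dff(ses)
      pks <- detect_peaks(dff,
                          min_prominence = config$photometry.min_prominence)
      summ <- bout_state_summary(dff, pks, bts)
      aligned <- align_to_onsets(dff, pks, bts,
                                 half_window_s =
                                   config$photometry.half_window_s)
      write.csv(
        data.frame(offset_s = aligned$offsets,
                   immobile_onset = aligned$column_means$immobile,
                   mobile_onset = aligned$column_means$mobile),
        file.path(out_dir, "peri_onset_means.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(per_state = summ$per_state, n_peaks = nrow(pks$peaks)),
        file.path(out_dir, "photometry_summary.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      list(dff = dff, peaks = pks, summary = summ, aligned = aligned)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors$photometry <- conditionMessage(res)
    } else results$photometry <- res
  }

  invisible(list(status = as.integer(length(errors) > 0L),
                 results = results, errors = errors))
}
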