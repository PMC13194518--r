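#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters with their defaults. Keys use
#' dotted `module.parameter` names. Values supplied as `...` or through a
#' YAML file (see [load_config()]) override the defaults; unknown keys are
#' rejected so typos never silently fall back to a default.
#'
#' @param ... named overrides, e.g. `score.threshold_g = 0.8`.
#'
#' @return A named list of configuration values.
#'
#' @details Defaults: heavy smoothing window 100 samples; start-detection
#' persistence 270 s with a +/- 30 s refinement search margin; baseline from
#' the minimum-variability 800-sample window; band-pass 1--20 Hz of overall
#' order 4 (zero phase); observation window 360 s; detection threshold
#' 0.792 g with a 0.25 s envelope span and no minimum bout duration; peak
#' prominence 0.5 SD and a +/- 1 s peri-onset window for photometry.
#'
#' @examples
#' cfg <- tst_config(score.threshold_g = 0.8)
#' cfg$score.threshold_g
#'
#' @export
tst_config <- function(...) {
  defaults <- list(
    smoothing.window_points = 100,
    start.persistence_s     = 270,
    start.search_margin_s   = 30,
    baseline.window_points  = 800,
    filter.band_hz          = c(1, 20),
    filter.order            = 4,
    window.duration_s       = 360,
    score.threshold_g       = 0.792,
    score.envelope_span_s   = 0.25,
    score.min_bout_s        = 0,
    calibration.grid_step_g = 0.001,
    calibration.train_frac  = 0.75,
    calibration.seed        = 42,
    photometry.min_prominence = 0.5,
    photometry.half_window_s  = 1.0
  )
  merge_config(defaults, list(...))
}

#' Load a configuration file and merge with defaults
#'
#' Reads a YAML file whose top-level keys are the dotted names of
#' [tst_config()] and merges it over the defaults; `...` overrides both.
#'
#' @param path path to a YAML file, or `NULL` for defaults only.
#' @param ... named overrides applied last.
#'
#' @return A named configuration list.
#' @export
load_config <- function(path = NULL, ...) {
  cfg <- tst_config()
  if (!is.null(path)) {
    stopifnot(file.exists(path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  merge_config(cfg, list(...))
}

merge_config <- function(base, overrides) {
  if (length(overrides) == 0L) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(nms, names(base))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[nms] <- overrides
  base
}
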