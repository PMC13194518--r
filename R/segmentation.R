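## Two-step session start detection and 360-s window extraction.
##
## Step 1: the raw trace is heavily smoothed (zero-phase 100-point moving
## average), a period threshold (0.9*mean + 0.1*min of the smoothed signal)
## separates the standing and suspended regimes, and the provisional start is
## the earliest time after which the smoothed signal stays above that
## threshold for at least 270 s. Step 2: a baseline is taken as the mean of
## the minimum-variability 800-sample window in the middle third of the
## post-start segment, and the start is refined to the first raw sample
## exceeding the baseline within +/- 30 s of the provisional start.

#' Zero-phase heavy smoothing (moving average, forward-backward)
#'
#' Applies a `window_points`-sample moving average forward and then backward
#' over the series, after padding by edge replication so boundary samples
#' see a full window. The forward-backward pass gives a symmetric (zero
#' phase) effective impulse response.
#'
#' @param x a [force_trace()] or numeric vector.
#' @param window_points moving-average length in samples (default 100).
#'
#' @return Numeric vector, same length as the input.
#' @export
heavy_smooth <- function(x, window_points = 100) {
  v <- if (inherits(x, "force_trace")) x$values else as.numeric(x)
  w <- as.integer(window_points)
  if (length(v) <= 2L * w) {
    stop("insufficient samples for smoothing", call. = FALSE)
  }
  pad <- 2L * w
  vp <- c(rep(v[1], pad), v, rep(v[length(v)], pad))
  k <- rep(1 / w, w)
  fwd <- as.numeric(stats::filter(vp, k, method = "convolution", sides = 1))
  bwd <- rev(as.numeric(stats::filter(rev(fwd), k, method = "convolution",
                                      sides = 1)))
  out <- bwd[(pad + 1L):(pad + length(v))]
  if (anyNA(out)) stop("insufficient samples for smoothing", call. = FALSE)
  out
}

#' Period threshold separating pre- and post-start regimes
#'
#' `0.9 * mean + 0.1 * min` of the heavily smoothed signal.
#'
#' @param smoothed numeric vector of smoothed force values (g).
#' @return threshold in grams.
#' @export
period_threshold <- function(smoothed) {
  smoothed <- as.numeric(smoothed)
  if (length(smoothed) == 0L) stop("empty input", call. = FALSE)
  0.9 * mean(smoothed) + 0.1 * min(smoothed)
}

#' Provisional session start from threshold persistence
#'
#' The earliest time t such that every sample in `[t, t + persistence_s)` is
#' strictly greater than `threshold`. The persistence window is
#' `ceiling(persistence_s * rate)` samples, closed-open.
#'
#' @param smoothed numeric vector of smoothed values.
#' @param threshold period threshold in grams.
#' @param timestamps sample timestamps (seconds), same length as `smoothed`.
#' @param persistence_s required persistence in seconds (default 270).
#'
#' @return provisional start time in seconds.
#' @export
provisional_start <- function(smoothed, threshold, timestamps,
                              persistence_s = 270) {
  smoothed <- as.numeric(smoothed)
  n <- length(smoothed)
  stopifnot(length(timestamps) == n)
  rate <- 1 / median(diff(timestamps))
  m <- as.integer(ceiling(persistence_s * rate))
  if (n < m) stop("series too short for persistence window", call. = FALSE)
  above <- smoothed > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= m)
  if (length(ok) == 0L) stop("no post-start period found", call. = FALSE)
  timestamps[starts[ok[1]]]
}

#' Baseline from the minimum-variability window
#'
#' Within the middle third of the post-start segment (from
#' `provisional_start` to the end of the trace), finds the contiguous
#' `window_points`-sample window with the smallest population standard
#' deviation (earliest window on ties) and returns its mean. This is the
#' suspended-weight plateau level used for start refinement and baseline
#' subtraction.
#'
#' @param trace a [force_trace()].
#' @param provisional_start provisional start time in seconds.
#' @param window_points window length in samples (default 800).
#'
#' @return baseline force in grams.
#' @export
estimate_baseline <- function(trace, provisional_start,
                              window_points = 800) {
  stopifnot(inherits(trace, "force_trace"))
  w <- as.integer(window_points)
  seg_idx <- which(trace$timestamps >= provisional_start)
  n_seg <- length(seg_idx)
  if (n_seg < 3L * w) {
    stop("post-start segment too short for baseline", call. = FALSE)
  }
  third <- floor(n_seg / 3)
  mid <- seg_idx[(third + 1L):(2L * third)]
  v <- trace$values[mid]
  nm <- length(v)
  ## rolling mean and population SD over every contiguous w-window in the
  ## middle third, via centered cumulative sums (centering keeps the
  ## cumulants small so the subtraction stays accurate)
  vc <- v - mean(v)
  cs <- c(0, cumsum(vc))
  cs2 <- c(0, cumsum(vc^2))
  i0 <- seq_len(nm - w + 1L)
  s1 <- cs[i0 + w] - cs[i0]
  s2 <- cs2[i0 + w] - cs2[i0]
  varw <- pmax(s2 / w - (s1 / w)^2, 0)
  best <- which.min(varw)
  mean(v[best:(best + w - 1L)])
}

#' Refine the session start to the first baseline exceedance
#'
#' Scans `[provisional_start - search_margin_s, provisional_start +
#' search_margin_s]` and returns the time of the first raw sample strictly
#' exceeding `baseline`. The search is local because a global scan would hit
#' spurious pre-start noise. If no sample in the interval exceeds the
#' baseline, the provisional start is returned with a warning.
#'
#' @param trace a [force_trace()].
#' @param baseline baseline force in grams.
#' @param provisional_start provisional start time (s).
#' @param search_margin_s half-width of the search interval (default 30 s).
#'
#' @return refined start time in seconds (always within
#'   `+/- search_margin_s` of the provisional start).
#' @export
refine_start <- function(trace, baseline, provisional_start,
                         search_margin_s = 30) {
  stopifnot(inherits(trace, "force_trace"), is.finite(baseline))
  idx <- which(trace$timestamps >= provisional_start - search_margin_s &
               trace$timestamps <= provisional_start + search_margin_s)
  if (length(idx) == 0L) stop("empty start search interval", call. = FALSE)
  hit <- idx[trace$values[idx] > baseline]
  if (length(hit) == 0L) {
    warning("no baseline crossing in search interval; keeping provisional start")
    return(provisional_start)
  }
  trace$timestamps[hit[1]]
}

zero_phase_bandpass <- function(x, rate, band_hz = c(1, 20), order = 4) {
  stopifnot(order %% 2 == 0, band_hz[1] > 0, band_hz[2] < rate / 2)
  ## signal::butter(n, ., "pass") yields a band-pass of polynomial order 2n;
  ## `order` names the overall band-pass order
  bf <- signal::butter(order / 2, band_hz / (rate / 2), type = "pass")
  n <- length(x)
  pad <- min(n - 1L, as.integer(3 * rate))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]),
          x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  fwd <- signal::filter(bf, xp)
  bwd <- rev(as.numeric(signal::filter(bf, rev(fwd))))
  bwd[(pad + 1L):(pad + n)]
}

#' Extract and filter the 360-s observation window
#'
#' Slices `[refined_start, refined_start + duration_s)` from the raw trace,
#' subtracts the baseline, and applies a zero-phase Butterworth band-pass
#' (default 1--20 Hz, overall order 4, forward-backward with
#' reflection padding).
#'
#' @param trace a [force_trace()].
#' @param refined_start refined start time (s).
#' @param baseline baseline force (g).
#' @param duration_s window duration (default 360 s).
#' @param band_hz band-pass corner frequencies in Hz.
#' @param order overall band-pass filter order (even).
#'
#' @return An object of class `filtered_window` with fields `timestamps`
#'   (seconds relative to the refined start), `values` (baseline-subtracted,
#'   band-passed force in g), and `rate` (Hz).
#' @export
extract_window <- function(trace, refined_start, baseline,
                           duration_s = 360, band_hz = c(1, 20), order = 4) {
  stopifnot(inherits(trace, "force_trace"))
  rate <- trace$nominal_rate
  n <- as.integer(round(duration_s * rate))
  i0 <- which(trace$timestamps >= refined_start - 1e-9)[1]
  if (is.na(i0) || i0 + n - 1L > length(trace$values)) {
    stop("recording truncated before 360 s window", call. = FALSE)
  }
  idx <- i0:(i0 + n - 1L)
  vals <- zero_phase_bandpass(trace$values[idx] - baseline, rate,
                              band_hz = band_hz, order = order)
  structure(
    list(timestamps = trace$timestamps[idx] - refined_start,
         values = vals, rate = rate),
    class = "filtered_window"
  )
}

#' @export
print.filtered_window <- function(x, ...) {
  cat(sprintf(
    "<filtered_window> %d samples at %g Hz, span %.2f s, RMS %.3f g\n",
    length(x$values), x$rate,
    length(x$values) / x$rate, sqrt(mean(x$values^2))))
  invisible(x)
}

#' Detect the session start and extract the analysis window
#'
#' Runs the full two-step procedure: heavy smoothing, period threshold,
#' persistence-based provisional start, minimum-variability baseline, local
#' start refinement, and extraction + band-pass filtering of the observation
#' window. A user-supplied `start_override` skips detection and places the
#' window at the given time (the baseline is still estimated from the
#' post-override segment for subtraction).
#'
#' @param trace a [force_trace()] covering at least the pre-start period
#'   plus the full observation window.
#' @param config configuration list from [tst_config()].
#' @param start_override optional manual start time in seconds.
#'
#' @return A list with components `segmentation` (class
#'   `session_segmentation`: `period_threshold`, `provisional_start`,
#'   `baseline`, `refined_start`, `window_span`) and `window`
#'   (a `filtered_window`).
#' @export
detect_session <- function(trace, config = tst_config(),
                           start_override = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(start_override)) {
    sm <- heavy_smooth(trace, config$smoothing.window_points)
    thr <- period_threshold(sm)
    prov <- provisional_start(sm, thr, trace$timestamps,
                              persistence_s = config$start.persistence_s)
    base <- estimate_baseline(trace, prov,
                              window_points = config$baseline.window_points)
    start <- refine_start(trace, base, prov,
                          search_margin_s = config$start.search_margin_s)
  } else {
    thr <- NA_real_
    prov <- start_override
    base <- estimate_baseline(trace, start_override,
                              window_points = config$baseline.window_points)
    start <- start_override
  }
  win <- extract_window(trace, start, base,
                        duration_s = config$window.duration_s,
                        band_hz = config$filter.band_hz,
                        order = config$filter.order)
  seg <- structure(
    list(period_threshold = thr, provisional_start = prov,
         baseline = base, refined_start = start,
         window_span = c(start, start + config$window.duration_s)),
    class = "session_segmentation"
  )
  list(segmentation = seg, window = win)
}

#' @export
print.session_segmentation <- function(x, ...) {
  cat(sprintf(
    paste0("<session_segmentation> start %.3f s (provisional %.3f s), ",
           "baseline %.3f g, window [%.3f, %.3f) s\n"),
    x$refined_start, x$provisional_start, x$baseline,
    x$window_span[1], x$window_span[2]))
  invisible(x)
}
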