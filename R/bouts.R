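## Envelope-threshold bout segmentation and behavioral outcome measures.

#' Movement envelope of a filtered window
#'
#' Rolling maximum of the rectified (absolute) band-passed signal over a
#' centered span. The band-passed struggle signal oscillates through zero,
#' so thresholding it directly would chop every oscillation cycle into
#' micro-bouts; the short rolling-max envelope tracks movement amplitude
#' instead.
#'
#' @param window a `filtered_window` (see [extract_window()]) or numeric
#'   vector (then `rate` must be given).
#' @param span_s envelope span in seconds (default 0.25; must cover at
#'   least 2 samples).
#' @param rate sampling rate in Hz, taken from the window if omitted.
#'
#' @return Numeric envelope, same length as the input.
#' @export
movement_envelope <- function(window, span_s = 0.25, rate = NULL) {
  if (inherits(window, "filtered_window")) {
    v <- window$values
    rate <- window$rate
  } else {
    v <- as.numeric(window)
    stopifnot(!is.null(rate))
  }
  k <- as.integer(round(span_s * rate))
  if (k < 2L) stop("envelope span too short", call. = FALSE)
  a <- abs(v)
  n <- length(a)
  half_before <- (k - 1L) %/% 2L
  env <- rep(-Inf, n)
  for (off in (-half_before):(k - 1L - half_before)) {
    src <- seq_len(n) + off
    valid <- src >= 1L & src <= n
    env[valid] <- pmax(env[valid], a[src[valid]])
  }
  env
}

#' Classify immobility/mobility states from the envelope
#'
#' A sample is mobile iff the envelope strictly exceeds `threshold`. Runs
#' shorter than `min_bout_s` are merged into the neighbouring state
#' (shortest run first; earliest first on ties) until none remain. The
#' default `min_bout_s = 0` performs no merging.
#'
#' @param envelope numeric movement envelope (g).
#' @param threshold detection threshold in grams (> 0).
#' @param rate sampling rate in Hz.
#' @param min_bout_s minimum bout duration in seconds (default 0).
#'
#' @return An object of class `bout_series`: per-sample logical `immobile`,
#'   `rate`, `threshold_used`, and a `bouts` data frame (`state`,
#'   `start_s`, `end_s` relative to the window start).
#' @export
classify_states <- function(envelope, threshold, rate, min_bout_s = 0) {
  stopifnot(threshold > 0, rate > 0)
  immobile <- !(as.numeric(envelope) > threshold)
  m <- as.integer(round(min_bout_s * rate))
  if (m > 1L) {
    repeat {
      r <- rle(immobile)
      if (length(r$lengths) <= 1L) break
      short <- which(r$lengths < m)
      if (length(short) == 0L) break
      pick <- short[order(r$lengths[short], short)][1]
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      immobile[starts[pick]:ends[pick]] <- !r$values[pick]
    }
  }
  r <- rle(immobile)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bouts <- data.frame(
    state = ifelse(r$values, "immobile", "mobile"),
    start_s = (starts - 1L) / rate,
    end_s = ends / rate
  )
  structure(
    list(immobile = immobile, rate = rate, threshold_used = threshold,
         bouts = bouts),
    class = "bout_series"
  )
}

#' @export
print.bout_series <- function(x, ...) {
  cat(sprintf(
    "<bout_series> %d bouts at %g Hz, threshold %.3f g, immobility %.1f s\n",
    nrow(x$bouts), x$rate, x$threshold_used,
    sum(x$immobile) / x$rate))
  invisible(x)
}

#' Convert a bout series to an annotation track
#'
#' @param bouts a `bout_series` from [classify_states()].
#' @param t0 absolute session time of the window start (s).
#' @return An [annotation_track()] with `source = "automated"`.
#' @export
as_annotation_track <- function(bouts, t0 = 0) {
  stopifnot(inherits(bouts, "bout_series"))
  annotation_track(
    data.frame(state = bouts$bouts$state,
               start_s = bouts$bouts$start_s + t0,
               end_s = bouts$bouts$end_s + t0),
    source = "automated", rate = bouts$rate)
}

#' Behavioral outcome measures of a scored session
#'
#' Total immobility time, immobility latency (onset of the first immobile
#' bout; the session duration if the animal is never immobile), the
#' cumulative immobility curve sampled at 1 s, and per-minute immobility.
#'
#' @param bouts a `bout_series` from [classify_states()].
#' @param subject_id subject identifier carried into reports.
#'
#' @return An object of class `score_summary` with fields `subject_id`,
#'   `total_immobility` (s), `latency` (s), `cumulative_curve` (data frame
#'   `time_s`, `immobility_s`), `per_minute` (immobility s per 60-s bin),
#'   `threshold_used` (g).
#' @export
summarize_bouts <- function(bouts, subject_id = "s1") {
  stopifnot(inherits(bouts, "bout_series"))
  rate <- bouts$rate
  n <- length(bouts$immobile)
  duration <- n / rate
  total <- sum(bouts$immobile) / rate
  first <- which(bouts$immobile)[1]
  latency <- if (is.na(first)) duration else (first - 1L) / rate
  csum <- c(0, cumsum(bouts$immobile))
  tgrid <- 0:floor(duration)
  cum <- csum[pmin(round(tgrid * rate), n) + 1L] / rate
  n_min <- ceiling(duration / 60)
  per_min <- vapply(seq_len(n_min), function(j) {
    lo <- round((j - 1L) * 60 * rate) + 1L
    hi <- min(round(j * 60 * rate), n)
    sum(bouts$immobile[lo:hi]) / rate
  }, numeric(1))
  structure(
    list(subject_id = subject_id, total_immobility = total,
         latency = latency,
         cumulative_curve = data.frame(time_s = tgrid, immobility_s = cum),
         per_minute = per_min, threshold_used = bouts$threshold_used),
    class = "score_summary"
  )
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf(
    "<score_summary> %s: immobility %.1f s, latency %.1f s (threshold %.3f g)\n",
    x$subject_id, x$total_immobility, x$latency, x$threshold_used))
  invisible(x)
}

#' Automated immobility time across candidate thresholds
#'
#' Scores the same filtered window at each threshold and reports the total
#' automated immobility time. Because a larger threshold can only reclassify
#' mobile samples as immobile, the result is non-decreasing in the
#' threshold.
#'
#' @param window a `filtered_window`.
#' @param thresholds numeric vector of candidate thresholds in grams
#'   (default the candidate set 0.4, 0.6, 0.8, 1.0, 1.2).
#' @param span_s envelope span in seconds.
#' @param min_bout_s minimum bout duration in seconds.
#'
#' @return data frame with columns `threshold`, `auto_time` (s).
#' @export
score_at_thresholds <- function(window, thresholds = c(0.4, 0.6, 0.8, 1.0, 1.2),
                                span_s = 0.25, min_bout_s = 0) {
  stopifnot(length(thresholds) > 0L, all(thresholds > 0))
  env <- movement_envelope(window, span_s = span_s)
  auto <- vapply(thresholds, function(th) {
    bs <- classify_states(env, th, rate = window$rate,
                          min_bout_s = min_bout_s)
    sum(bs$immobile) / bs$rate
  }, numeric(1))
  data.frame(threshold = thresholds, auto_time = auto)
}
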