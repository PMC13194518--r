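## Fiber-photometry processing: robust isosbestic regression, dF/F and
## z-scoring, topographic-prominence transient detection, bout-state
## summaries, and event-pure peri-onset alignment of calcium signals to
## behavioral transitions.

#' Construct a two-channel photometry session
#'
#' @param timestamps strictly increasing seconds (shared session clock).
#' @param signal_470 calcium-dependent 470 nm fluorescence (a.u.).
#' @param control_415 isosbestic 415 nm fluorescence (a.u.).
#' @param rate sampling rate in Hz (default 40).
#'
#' @return object of class `photometry_session`.
#' @export
photometry_session <- function(timestamps, signal_470, control_415,
                               rate = 40) {
  timestamps <- as.numeric(timestamps)
  signal_470 <- as.numeric(signal_470)
  control_415 <- as.numeric(control_415)
  stopifnot(length(timestamps) == length(signal_470),
            length(timestamps) == length(control_415), rate > 0)
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(
    list(timestamps = timestamps, signal_470 = signal_470,
         control_415 = control_415, rate = rate),
    class = "photometry_session"
  )
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session> %d samples at %g Hz, %.1f s\n",
              length(x$timestamps), x$rate,
              x$timestamps[length(x$timestamps)] - x$timestamps[1]))
  invisible(x)
}

#' Read a photometry CSV (`time_s, sig_470, ctl_415`)
#'
#' A single-stream file with an `led_state` column (415/470) is
#' deinterleaved onto the 470-frame timestamps by nearest-sample pairing.
#'
#' @param path path to the CSV.
#' @param rate sampling rate per channel in Hz.
#' @return a [photometry_session()].
#' @export
read_photometry <- function(path, rate = 40) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("time_s", "sig_470", "ctl_415") %in% names(df))) {
    return(photometry_session(df$time_s, df$sig_470, df$ctl_415,
                              rate = rate))
  }
  if (all(c("time_s", "value", "led_state") %in% names(df))) {
    s470 <- df[df$led_state == 470, , drop = FALSE]
    s415 <- df[df$led_state == 415, , drop = FALSE]
    ctl <- approx(s415$time_s, s415$value, xout = s470$time_s,
                  method = "constant", rule = 2)$y
    return(photometry_session(s470$time_s, s470$value, ctl, rate = rate))
  }
  stop("unrecognized photometry layout", call. = FALSE)
}

#' Robust fit of the isosbestic control to the calcium channel
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685, at most 50 iterations): the motion/drift control
#' is scaled and shifted onto the 470 nm signal while calcium transients are
#' downweighted as outliers.
#'
#' @param session a [photometry_session()] (>= 100 samples).
#' @return list of class `control_fit`: `fitted` (a.u.), `slope`,
#'   `intercept`.
#' @export
fit_control <- function(session) {
  stopifnot(inherits(session, "photometry_session"))
  if (length(session$timestamps) < 100L) {
    stop("session too short for control fit", call. = FALSE)
  }
  if (sd(session$control_415) == 0) {
    stop("degenerate control channel", call. = FALSE)
  }
  fit <- MASS::rlm(session$signal_470 ~ session$control_415,
                   psi = MASS::psi.bisquare, c = 4.685, maxit = 50)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  structure(
    list(fitted = intercept + slope * session$control_415,
         slope = slope, intercept = intercept),
    class = "control_fit"
  )
}

#' Motion-corrected dF/F and z-score
#'
#' `dF/F = (F - F_fitted_iso) / F_fitted_iso` with the robustly fitted
#' isosbestic as `F_fitted_iso`, followed by z-scoring over the whole
#' session.
#'
#' @param session a [photometry_session()].
#' @param control_fit a [fit_control()] result; computed if omitted.
#' @return object of class `dff_trace`: `timestamps`, `dff`, `zscore`,
#'   `fitted_control`, `fit_slope`, `fit_intercept`, `rate`.
#' @export
compute_dff <- function(session, control_fit = NULL) {
  stopifnot(inherits(session, "photometry_session"))
  if (is.null(control_fit)) control_fit <- fit_control(session)
  fitted <- control_fit$fitted
  if (any(fitted <= 0)) {
    stop("non-positive fitted control", call. = FALSE)
  }
  dff <- (session$signal_470 - fitted) / fitted
  s <- sd(dff)
  if (s < 1e-10) {
    ## a perfectly explained signal (dff identically 0) has no activity to
    ## standardize: its z-score is 0 by convention; any other constant dff
    ## has an undefined z-score
    if (max(abs(dff)) > 1e-10) stop("constant dff", call. = FALSE)
    zscore <- rep(0, length(dff))
  } else {
    zscore <- (dff - mean(dff)) / s
  }
  structure(
    list(timestamps = session$timestamps, dff = dff,
         zscore = zscore,
         fitted_control = fitted, fit_slope = control_fit$slope,
         fit_intercept = control_fit$intercept, rate = session$rate),
    class = "dff_trace"
  )
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf(
    "<dff_trace> %d samples at %g Hz, fit slope %.3f, dff SD %.4f\n",
    length(x$dff), x$rate, x$fit_slope, sd(x$dff)))
  invisible(x)
}

#' @export
plot.dff_trace <- function(x, ...) {
  plot(x$timestamps, x$zscore, type = "l", xlab = "time (s)",
       ylab = "z-scored dF/F", ...)
  invisible(x)
}

#' Detect calcium transients by topographic prominence
#'
#' Strict local maxima whose topographic prominence (height above the
#' higher of the two minima separating the peak from larger neighbours, or
#' from the series edge) reaches `min_prominence`. Amplitude is the
#' z-score at the peak sample.
#'
#' @param trace a `dff_trace` or numeric z-score series.
#' @param min_prominence prominence floor in SD units (default 0.5).
#' @param timestamps sample times; taken from the trace if omitted.
#'
#' @return object of class `peak_set`: data frame `peaks` with columns
#'   `index`, `time`, `amplitude`, `prominence`.
#' @export
detect_peaks <- function(trace, min_prominence = 0.5, timestamps = NULL) {
  if (inherits(trace, "dff_trace")) {
    x <- trace$zscore
    timestamps <- trace$timestamps
  } else {
    x <- as.numeric(trace)
    if (is.null(timestamps)) timestamps <- seq_along(x) - 1
  }
  n <- length(x)
  stopifnot(n >= 3L)
  is_peak <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                   x[2:(n - 1L)] > x[3:n]) + 1L
  prom <- vapply(is_peak, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= min_prominence
  structure(
    list(peaks = data.frame(index = is_peak[keep],
                            time = timestamps[is_peak[keep]],
                            amplitude = x[is_peak[keep]],
                            prominence = prom[keep])),
    class = "peak_set"
  )
}

peak_prominence <- function(x, i) {
  h <- x[i]
  n <- length(x)
  left_min <- h
  j <- i - 1L
  found <- FALSE
  while (j >= 1L) {
    if (x[j] > h) { found <- TRUE; break }
    if (x[j] < left_min) left_min <- x[j]
    j <- j - 1L
  }
  if (!found && i > 1L) left_min <- min(x[1:(i - 1L)])
  right_min <- h
  j <- i + 1L
  found <- FALSE
  while (j <= n) {
    if (x[j] > h) { found <- TRUE; break }
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  if (!found && i < n) right_min <- min(x[(i + 1L):n])
  h - max(left_min, right_min)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks\n", nrow(x$peaks)))
  invisible(x)
}

#' Calcium activity summarized by behavioral state
#'
#' Per bout: area under the z-score curve per second (trapezoidal), peak
#' frequency (peaks per second), and mean peak amplitude; then bout-wise
#' means per state (immobile vs mobile).
#'
#' @param dff a `dff_trace` on the shared session clock.
#' @param peaks a `peak_set` from [detect_peaks()].
#' @param bouts a `bout_series` or [annotation_track()].
#' @param bouts_t0 absolute session time of the bout-series origin
#'   (ignored for annotation tracks, which are already absolute).
#'
#' @return list with `per_bout` (data frame: `state`, `start_s`, `end_s`,
#'   `auc_per_s`, `peak_freq_hz`, `peak_amplitude`) and `per_state`
#'   (bout-wise means per state).
#' @export
bout_state_summary <- function(dff, peaks, bouts, bouts_t0 = 0) {
  stopifnot(inherits(dff, "dff_trace"), inherits(peaks, "peak_set"))
  bt <- bout_table(bouts, bouts_t0)
  t <- dff$timestamps
  if (max(bt$end_s) < t[1] || min(bt$start_s) > t[length(t)]) {
    stop("clocks not aligned", call. = FALSE)
  }
  per_bout <- do.call(rbind, lapply(seq_len(nrow(bt)), function(k) {
    s <- bt$start_s[k]; e <- bt$end_s[k]
    idx <- which(t >= s & t < e)
    auc <- if (length(idx) >= 2L) {
      trapz(t[idx], dff$zscore[idx]) / (e - s)
    } else NA_real_
    pk <- peaks$peaks$time >= s & peaks$peaks$time < e
    data.frame(state = bt$state[k], start_s = s, end_s = e,
               auc_per_s = auc, peak_freq_hz = sum(pk) / (e - s),
               peak_amplitude = if (any(pk)) {
                 mean(peaks$peaks$amplitude[pk])
               } else NA_real_)
  }))
  per_state <- do.call(rbind, lapply(c("immobile", "mobile"), function(st) {
    sub <- per_bout[per_bout$state == st, , drop = FALSE]
    data.frame(state = st,
               auc_per_s = mean(sub$auc_per_s, na.rm = TRUE),
               peak_freq_hz = mean(sub$peak_freq_hz, na.rm = TRUE),
               peak_amplitude = mean(sub$peak_amplitude, na.rm = TRUE),
               n_bouts = nrow(sub))
  }))
  list(per_bout = per_bout, per_state = per_state)
}

bout_table <- function(bouts, bouts_t0 = 0) {
  if (inherits(bouts, "annotation_track")) {
    bouts$bouts
  } else if (inherits(bouts, "bout_series")) {
    data.frame(state = bouts$bouts$state,
               start_s = bouts$bouts$start_s + bouts_t0,
               end_s = bouts$bouts$end_s + bouts_t0)
  } else stop("bouts must be a bout_series or annotation_track",
              call. = FALSE)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Event-pure peri-onset alignment of calcium signals
#'
#' For each bout onset, extracts the z-score on a fixed grid spanning
#' `[-half_window_s, +half_window_s]` around the onset. Samples before the
#' onset must lie inside the immediately preceding bout and samples at or
#' after it inside the current bout; anything else (including samples past
#' the session edge) is masked and never contributes to an average. Events
#' with no valid cell are dropped. Peri-onset peak counts and amplitudes
#' are computed from the same event-pure intervals.
#'
#' @param dff a `dff_trace`.
#' @param peaks a `peak_set`.
#' @param bouts a `bout_series` or [annotation_track()].
#' @param half_window_s half-window in seconds (default 1).
#' @param bouts_t0 absolute time of the bout-series origin.
#'
#' @return object of class `event_aligned`: `matrix` (events x grid,
#'   masked cells `NA`), `valid` (logical mask), `offsets` (s),
#'   `event_state`, `event_onset`, `events` (per-event pre/post peak
#'   counts and mean amplitudes), `column_means` (named list per state of
#'   masked column means).
#' @export
align_to_onsets <- function(dff, peaks, bouts, half_window_s = 1,
                            bouts_t0 = 0) {
  stopifnot(inherits(dff, "dff_trace"))
  bt <- bout_table(bouts, bouts_t0)
  rate <- dff$rate
  t0 <- dff$timestamps[1]
  n <- length(dff$zscore)
  H <- as.integer(round(half_window_s * rate))
  offsets <- (-H:H) / rate
  keep_ev <- seq_len(nrow(bt))[-1]
  mat <- NULL; valid <- NULL
  ev_state <- character(0); ev_onset <- numeric(0)
  ev_rows <- list()
  for (k in keep_ev) {
    onset <- bt$start_s[k]
    prev_start <- bt$start_s[k - 1L]
    cur_end <- bt$end_s[k]
    tt <- onset + offsets
    idx <- round((tt - t0) * rate) + 1L
    ok_session <- idx >= 1L & idx <= n
    ok_bout <- ifelse(offsets < 0,
                      tt >= prev_start, tt < cur_end)
    ok <- ok_session & ok_bout
    if (!any(ok)) next
    row <- rep(NA_real_, length(offsets))
    row[ok] <- dff$zscore[idx[ok]]
    mat <- rbind(mat, row)
    valid <- rbind(valid, ok)
    ev_state <- c(ev_state, bt$state[k])
    ev_onset <- c(ev_onset, onset)
    pre_lo <- max(prev_start, onset - half_window_s)
    post_hi <- min(cur_end, onset + half_window_s)
    pt <- peaks$peaks$time
    pre <- pt >= pre_lo & pt < onset
    post <- pt >= onset & pt <= post_hi
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      state = bt$state[k], onset = onset,
      pre_count = sum(pre), post_count = sum(post),
      pre_amplitude = if (any(pre)) mean(peaks$peaks$amplitude[pre])
                      else NA_real_,
      post_amplitude = if (any(post)) mean(peaks$peaks$amplitude[post])
                       else NA_real_)
  }
  if (is.null(mat)) stop("no alignable events", call. = FALSE)
  dimnames(mat) <- NULL; dimnames(valid) <- NULL
  events <- do.call(rbind, ev_rows)
  column_means <- lapply(c(immobile = "immobile", mobile = "mobile"),
    function(st) {
      rows <- which(ev_state == st)
      if (length(rows) == 0L) return(rep(NA_real_, length(offsets)))
      colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    })
  structure(
    list(matrix = mat, valid = valid, offsets = offsets,
         event_state = ev_state, event_onset = ev_onset,
         events = events, column_means = column_means,
         half_window_s = half_window_s),
    class = "event_aligned"
  )
}

#' @export
print.event_aligned <- function(x, ...) {
  cat(sprintf(
    "<event_aligned> %d events (%d immobile-onset, %d mobile-onset), window +/- %g s\n",
    length(x$event_state), sum(x$event_state == "immobile"),
    sum(x$event_state == "mobile"), x$half_window_s))
  invisible(x)
}

#' Compare peri-onset peak counts between mobility and immobility onsets
#'
#' Plain two-sample t statistic on per-event peak counts in the
#' `[-half_window, +half_window]` event-pure window (mobile onsets vs
#' immobile onsets); descriptive, not an inferential battery.
#'
#' @param aligned an `event_aligned` from [align_to_onsets()].
#' @return the `htest` object from [stats::t.test()].
#' @export
peri_onset_peak_test <- function(aligned) {
  stopifnot(inherits(aligned, "event_aligned"))
  counts <- aligned$events$pre_count + aligned$events$post_count
  t.test(counts[aligned$events$state == "mobile"],
         counts[aligned$events$state == "immobile"])
}
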