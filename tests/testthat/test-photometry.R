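## shared small photometry fixtures
quiet_session <- function(n = 2000, rate = 40, seed = 101) {
  set.seed(seed)
  t <- (0:(n - 1)) / rate
  ctl <- 100 + 5 * sin(2 * pi * t / 60) + rnorm(n, sd = 0.5)
  photometry_session(t, 2 * ctl + 5, ctl, rate = rate)
}

test_that("robust control fit recovers an exact linear relation", {
  ses <- quiet_session()
  ## the near-exact fit can leave the IRLS weights oscillating at the
  ## 50-iteration cap; the estimate itself is stable
  fit <- suppressWarnings(fit_control(ses))
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_equal(fit$intercept, 5, tolerance = 1e-4)
  expect_equal(fit$fitted, ses$signal_470, tolerance = 1e-6)
})

test_that("the bisquare fit shrugs off sparse large transients where OLS drifts", {
  set.seed(103)
  n <- 4000; rate <- 40
  t <- (0:(n - 1)) / rate
  ctl <- 100 + 10 * sin(2 * pi * t / 80) + rnorm(n, sd = 0.3)
  sig <- 2 * ctl + 5
  hit <- sample(n, n * 0.01)
  sig[hit] <- sig[hit] + 80          # large positive transients
  ses <- photometry_session(t, sig, ctl)
  fit <- fit_control(ses)
  expect_lt(abs(fit$slope - 2), 0.05)
  ols <- coef(lm(sig ~ ctl))
  expect_gt(abs(ols[2] - 2) + abs(ols[1] - 5),
            abs(fit$slope - 2) + abs(fit$intercept - 5))
  expect_error(fit_control(photometry_session(t, sig, rep(100, n))),
               "degenerate control channel")
})

test_that("dF/F is zero for a perfectly explained signal and rejects degenerates", {
  ses <- quiet_session()
  fitted <- list(fitted = ses$signal_470, slope = 2, intercept = 5)
  dff <- compute_dff(ses, fitted)
  expect_equal(max(abs(dff$dff)), 0)
  ## constant dff has undefined z-score
  f2 <- list(fitted = ses$signal_470 / 1.1, slope = 2, intercept = 5)
  expect_error(compute_dff(ses, f2), "constant dff")
  f3 <- list(fitted = rep(-1, length(ses$timestamps)))
  expect_error(compute_dff(ses, f3), "non-positive fitted control")
})

test_that("z-scores are standardized and z-scoring is idempotent", {
  ses <- simulate_photometry(simple_track(c(100), t1 = 360),
                             seed = 7)$session
  dff <- compute_dff(ses)
  expect_lt(abs(mean(dff$zscore)), 1e-6)
  expect_equal(sd(dff$zscore), 1, tolerance = 1e-6)
  z2 <- (dff$zscore - mean(dff$zscore)) / sd(dff$zscore)
  expect_equal(z2, dff$zscore, tolerance = 1e-9)
})

test_that("shared multiplicative drift cancels without transients", {
  tr <- simple_track(c(50, 120, 300), t1 = 360)
  ph <- simulate_photometry(tr, transient_amp_dff = 0, seed = 17)
  dff <- compute_dff(ph$session)
  expect_lt(max(abs(dff$dff)), 0.02)
})

test_that("peak detection equals the brute-force prominence oracle", {
  set.seed(111)
  for (i in 1:5) {
    x <- as.numeric(stats::filter(rnorm(3000), rep(1 / 4, 4),
                                  sides = 1))
    x[is.na(x)] <- 0
    pk <- detect_peaks(x, min_prominence = 0.5)
    orc <- oracle_peaks(x, 0.5)
    expect_equal(pk$peaks$index, orc$index)
    expect_equal(pk$peaks$prominence, orc$prominence, tolerance = 1e-12)
  }
  expect_equal(nrow(detect_peaks(rep(0, 100))$peaks), 0L)
})

test_that("a single bump yields one peak with its height as prominence", {
  t <- seq(-5, 5, by = 0.025)
  x <- exp(-t^2 / 0.5)
  pk <- detect_peaks(x, min_prominence = 0.5)
  expect_equal(nrow(pk$peaks), 1L)
  expect_equal(pk$peaks$amplitude, 1, tolerance = 1e-9)
  expect_equal(pk$peaks$prominence, 1, tolerance = 1e-6)
})

test_that("injected transients are recovered at prominence 0.5", {
  ses <- simulate_session(sim_config(seed = 3))
  ph <- simulate_photometry(ses$truth_bouts, seed = 11)
  dff <- compute_dff(ph$session)
  pk <- detect_peaks(dff)
  hit <- vapply(ph$transient_times, function(te) {
    any(pk$peaks$time >= te & pk$peaks$time <= te + 0.4)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  fp <- vapply(pk$peaks$time, function(tp) {
    !any(tp >= ph$transient_times & tp <= ph$transient_times + 0.6)
  }, logical(1))
  expect_lte(mean(fp), 0.1)
})

test_that("bout-state summaries match trapezoid and counting oracles", {
  rate <- 40
  t <- (0:(40 * rate - 1)) / rate
  z <- rep(2, length(t))                       # constant z-score
  dff <- structure(list(timestamps = t, dff = z / 10, zscore = z,
                        fitted_control = rep(100, length(t)),
                        fit_slope = 1, fit_intercept = 0, rate = rate),
                   class = "dff_trace")
  bouts <- simple_track(c(10, 20, 30), t0 = 0, t1 = 40, rate = rate)
  peaks <- structure(list(peaks = data.frame(
    index = 1:3, time = c(11, 15, 19.5), amplitude = c(1, 2, 3),
    prominence = rep(1, 3))), class = "peak_set")
  sm <- bout_state_summary(dff, peaks, bouts)
  expect_equal(sm$per_bout$auc_per_s, rep(2, 4), tolerance = 0.01)
  ## 3 peaks inside the [10, 20) bout -> 0.3 Hz
  expect_equal(sm$per_bout$peak_freq_hz[2], 0.3)
  expect_equal(sm$per_bout$peak_amplitude[2], 2)
  expect_error(bout_state_summary(dff, peaks,
                                  simple_track(c(500), t0 = 400, t1 = 600)),
               "clocks not aligned")
})

test_that("peri-onset alignment masks non-event-pure samples", {
  rate <- 40
  t <- (0:(60 * rate - 1)) / rate
  z <- sin(2 * pi * t / 7)
  dff <- structure(list(timestamps = t, dff = z, zscore = z,
                        fitted_control = rep(1, length(t)),
                        fit_slope = 1, fit_intercept = 0, rate = rate),
                   class = "dff_trace")
  peaks <- structure(list(peaks = data.frame(index = integer(0),
                                             time = numeric(0),
                                             amplitude = numeric(0),
                                             prominence = numeric(0))),
                     class = "peak_set")
  ## long bouts either side of the 20-s onset: fully unmasked row
  bouts <- simple_track(c(20, 40), t0 = 0, t1 = 60, rate = rate)
  al <- align_to_onsets(dff, peaks, bouts)
  expect_true(all(al$valid[1, ]))
  ## short 0.4-s preceding bout: first 0.6 s of the pre-window masked
  bouts2 <- simple_track(c(19.6, 20, 45), t0 = 0, t1 = 60, rate = rate)
  al2 <- align_to_onsets(dff, peaks, bouts2)
  row <- which(abs(al2$event_onset - 20) < 1e-9)
  pre_masked <- !al2$valid[row, al2$offsets < -0.4 - 1e-9]
  expect_true(all(pre_masked))
  expect_true(all(al2$valid[row, al2$offsets >= -0.4 - 1e-9 &
                                 al2$offsets <= 1]))
})

test_that("masked cells never leak into any average (sentinel test)", {
  ses <- simulate_session(sim_config(seed = 5))
  ph <- simulate_photometry(ses$truth_bouts, seed = 19)
  dff <- compute_dff(ph$session)
  pk <- detect_peaks(dff)
  al <- align_to_onsets(dff, pk, ses$truth_bouts)

  ## poison every sample outside the event-pure regions used by any event
  poisoned <- dff
  used <- rep(FALSE, length(dff$zscore))
  t0 <- dff$timestamps[1]
  for (r in seq_along(al$event_onset)) {
    tt <- al$event_onset[r] + al$offsets[al$valid[r, ]]
    used[round((tt - t0) * dff$rate) + 1L] <- TRUE
  }
  poisoned$zscore[!used] <- 1e6
  al2 <- align_to_onsets(poisoned, pk, ses$truth_bouts)
  expect_identical(al$valid, al2$valid)
  expect_equal(al2$column_means$mobile, al$column_means$mobile,
               tolerance = 1e-12)
  expect_equal(al2$column_means$immobile, al$column_means$immobile,
               tolerance = 1e-12)
})

test_that("mobility-locked transients raise peri-mobility-onset peak counts", {
  ses <- simulate_session(sim_config(seed = 21))
  ph <- simulate_photometry(ses$truth_bouts, seed = 23)
  dff <- compute_dff(ph$session)
  pk <- detect_peaks(dff)
  al <- align_to_onsets(dff, pk, ses$truth_bouts)
  counts <- al$events$pre_count + al$events$post_count
  expect_gt(mean(counts[al$events$state == "mobile"]),
            mean(counts[al$events$state == "immobile"]))
})
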