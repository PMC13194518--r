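test_that("heavy smoothing is exact on constants and zero-phase on impulses", {
  expect_equal(heavy_smooth(rep(7.5, 1000)), rep(7.5, 1000),
               tolerance = 1e-12)
  x <- rep(0, 1001)
  x[501] <- 1
  sm <- heavy_smooth(x)
  expect_equal(sm, rev(sm), tolerance = 1e-12)
  expect_error(heavy_smooth(rep(1, 150)), "insufficient samples")
})

test_that("heavy smoothing equals the double-convolution oracle", {
  set.seed(11)
  x <- cumsum(rnorm(5000)) + 25
  expect_equal(heavy_smooth(x), oracle_heavy_smooth(x), tolerance = 1e-9)
})

test_that("period threshold follows the weighted mean/min formula", {
  expect_equal(period_threshold(c(18, 2, 10)), 0.9 * 10 + 0.1 * 2)
  expect_equal(period_threshold(rep(3.3, 50)), 3.3)
  set.seed(2)
  x <- runif(1000, 0, 30)
  expect_equal(period_threshold(x), 0.9 * mean(x) + 0.1 * min(x),
               tolerance = 1e-12)
  expect_error(period_threshold(numeric(0)), "empty input")
})

test_that("provisional start honors strict persistence", {
  rate <- 80
  t <- (0:(600 * rate - 1)) / rate
  x <- ifelse(t < 100, 5, 25)
  expect_equal(provisional_start(x, 10, t), 100)

  x2 <- rep(5, length(t))
  x2[t >= 50 & t < 60] <- 25   # 10-s excursion fails the 270-s persistence
  x2[t >= 120] <- 25
  expect_equal(provisional_start(x2, 10, t), 120)

  expect_error(provisional_start(rep(5, length(t)), 10, t),
               "no post-start period found")
})

test_that("provisional start equals the exhaustive persistence scan", {
  set.seed(21)
  rate <- 10
  t <- (0:1999) / rate
  for (i in 1:10) {
    x <- cumsum(rnorm(2000, sd = 0.5))
    thr <- quantile(x, runif(1, 0.2, 0.8))
    got <- tryCatch(provisional_start(x, thr, t, persistence_s = 30),
                    error = function(e) NA_real_)
    expect_equal(got, oracle_provisional_start(x, thr, t, 30))
  }
})

test_that("raising the threshold never yields an earlier provisional start", {
  set.seed(31)
  rate <- 10
  t <- (0:1999) / rate
  x <- cumsum(rnorm(2000, sd = 0.3)) + 10
  thrs <- quantile(x, c(0.1, 0.3, 0.5))
  starts <- vapply(thrs, function(th) {
    tryCatch(provisional_start(x, th, t, persistence_s = 20),
             error = function(e) Inf)
  }, numeric(1))
  expect_true(all(diff(starts) >= 0))
})

test_that("baseline finds the flat plateau and matches the exhaustive scan", {
  set.seed(41)
  rate <- 80
  trace <- step_trace(hang = 50, total = 250, noise_sd = 0.2, seed = 41)
  ## plant an exactly flat run inside the middle third of the post-start
  post <- which(trace$timestamps >= 50)
  third <- floor(length(post) / 3)
  mid <- post[(third + 1):(2 * third)]
  flat <- mid[2000:2799]
  trace$values[flat] <- 24.75
  expect_equal(estimate_baseline(trace, 50), 24.75)
  expect_equal(estimate_baseline(trace, 50), oracle_baseline(trace, 50),
               tolerance = 1e-9)
})

test_that("baseline matches the exhaustive scan on noisy traces and breaks ties early", {
  trace <- step_trace(hang = 40, total = 200, noise_sd = 0.15, seed = 43)
  expect_equal(estimate_baseline(trace, 40), oracle_baseline(trace, 40),
               tolerance = 1e-9)

  ## two identical flat windows: the earlier one must win
  tr2 <- step_trace(hang = 10, total = 130, noise_sd = 0.3, seed = 44)
  post <- which(tr2$timestamps >= 10)
  third <- floor(length(post) / 3)
  mid <- post[(third + 1):(2 * third)]
  tr2$values[mid[101:900]] <- 30      # earlier flat window, mean 30
  tr2$values[mid[1201:2000]] <- 20    # later flat window, mean 20
  expect_equal(estimate_baseline(tr2, 10), 30)
  expect_error(estimate_baseline(step_trace(total = 60), 55),
               "too short for baseline")
})

test_that("start refinement finds the first exceedance within the margin", {
  trace <- step_trace(hang = 100, total = 600)
  expect_equal(refine_start(trace, 24, 100.3), 100.0)
  ## always above baseline: left edge of the search interval
  expect_equal(refine_start(trace, 4, 200), 170)
  expect_warning(got <- refine_start(trace, 30, 100.3),
                 "keeping provisional")
  expect_equal(got, 100.3)
})

test_that("refinement equals a brute-force first-exceedance scan on noisy steps", {
  for (seed in 1:5) {
    trace <- step_trace(hang = 100, total = 600, noise_sd = 0.13,
                        seed = seed)
    base <- 24.9
    got <- refine_start(trace, base, 100.4)
    idx <- which(trace$timestamps >= 100.4 - 30 &
                 trace$timestamps <= 100.4 + 30)
    brute <- trace$timestamps[idx[which(trace$values[idx] > base)[1]]]
    expect_identical(got, brute)
  }
})

test_that("window extraction removes DC and has the stated band edges", {
  rate <- 80
  t <- (0:(500 * rate - 1)) / rate
  trace <- force_trace(t, rep(25, length(t)), nominal_rate = rate)
  win <- extract_window(trace, 50, 25)
  expect_equal(length(win$values), 360 * rate)
  expect_equal(max(abs(win$values)), 0, tolerance = 1e-9)

  for (f in c(5, 0.1)) {
    trace_s <- force_trace(t, 25 + sin(2 * pi * f * t), nominal_rate = rate)
    win_s <- extract_window(trace_s, 50, 25)
    core <- win_s$values[(5 * rate):(355 * rate)]
    amp <- max(abs(core))
    if (f == 5) expect_true(amp >= 0.95 && amp <= 1.05)
    else expect_lt(amp, 0.05)
  }
  expect_error(extract_window(trace, 200, 25), "truncated before 360")
})

test_that("filtered window mean is near zero and energy below the plateau", {
  ses <- simulate_session(sim_config(seed = 8))
  det <- detect_session(ses$trace)
  expect_lt(abs(mean(det$window$values)), 0.1)
  expect_lt(mean(abs(det$window$values)), ses$config$weight_g)
})

test_that("session detection recovers a known hang time within 0.5 s", {
  ses <- simulate_session(sim_config(seed = 123, hang_time_s = 120))
  det <- detect_session(ses$trace)
  expect_lt(abs(det$segmentation$refined_start - 120), 0.5)
  expect_lt(abs(det$segmentation$provisional_start - 120), 30)
})

test_that("manual start override fixes the window regardless of detection", {
  ses <- simulate_session(sim_config(seed = 9, hang_time_s = 95))
  det <- detect_session(ses$trace, start_override = 90)
  expect_equal(det$segmentation$refined_start, 90)
  expect_equal(det$segmentation$window_span, c(90, 450))
  expect_equal(length(det$window$values), 360 * 80)
})

test_that("segmentation is bit-identical across repeated runs", {
  ses <- simulate_session(sim_config(seed = 10))
  d1 <- detect_session(ses$trace)
  d2 <- detect_session(ses$trace)
  expect_identical(d1$segmentation, d2$segmentation)
  expect_identical(d1$window$values, d2$window$values)
})

test_that("smoothing and filtering leave a step edge at zero lag", {
  rate <- 80
  t <- (0:(599 * rate)) / rate
  x <- ifelse(t < 300, 0, 10)
  sm <- heavy_smooth(x)
  ## midpoint crossing of the smoothed edge should sit at the step
  cross <- which(sm >= 5)[1]
  edge <- which(x >= 5)[1]
  expect_lte(abs(cross - edge), 1)
})
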