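## Ground-truthed synthetic data: load-cell sessions with a standing
## pre-start baseline, a step to the suspended-weight plateau at a known
## hang time, band-limited struggle bursts during mobile bouts, Gaussian
## sensor noise; 30-fps manual annotations derived from the truth; cohorts
## with a treatment-like immobility reduction; and coupled two-channel
## photometry with shared multiplicative drift and mobility-locked calcium
## transients.

#' Simulation configuration
#'
#' Defaults describe a typical recording: 80 Hz sampling, a ~25.5 g mouse
#' standing with ~20% of its weight on the tail before the platform drops,
#' suspension at `hang_time_s`, sensor noise SD 0.13 g (~ +/- 0.4 g peak
#' excursions), struggle bursts band-limited to 2--10 Hz with
#' amplitude-modulated envelope (scale 3 g), and an alternating renewal
#' bout schedule with exponential durations (mean immobile bout 12 s)
#' tuned to an immobility fraction of 0.6.
#'
#' @param seed RNG seed; every generated artifact is a pure function of the
#'   configuration including this seed.
#' @param rate sampling rate (Hz).
#' @param pre_start_s standing period before the hang time (s).
#' @param hang_time_s true session start (platform removal) (s).
#' @param weight_g suspended weight (g).
#' @param standing_force_fraction fraction of the weight resting on the
#'   tail while the mouse stands.
#' @param noise_sd_g Gaussian sensor noise SD (g).
#' @param burst_band_hz struggle-burst frequency band, inside (1, 20) Hz so
#'   bursts survive the analysis band-pass.
#' @param burst_amplitude_g scale of the burst amplitude envelope (g).
#' @param mean_immobile_s mean immobile bout duration (s).
#' @param immobility_fraction_target long-run immobile fraction of the
#'   session; the mean mobile bout duration is derived from it.
#' @param min_bout_s floor on simulated bout durations (s).
#' @param session_s observation-window duration (s).
#' @param tail_s extra recording beyond the window (s).
#' @param first_state state of the first post-start bout.
#'
#' @return validated configuration list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, rate = 80, pre_start_s = 90,
                       hang_time_s = 90, weight_g = 25,
                       standing_force_fraction = 0.2, noise_sd_g = 0.13,
                       burst_band_hz = c(2, 10), burst_amplitude_g = 3,
                       mean_immobile_s = 12,
                       immobility_fraction_target = 0.6,
                       min_bout_s = 0.5, session_s = 360, tail_s = 15,
                       first_state = "mobile") {
  cfg <- list(seed = seed, rate = rate, pre_start_s = pre_start_s,
              hang_time_s = hang_time_s, weight_g = weight_g,
              standing_force_fraction = standing_force_fraction,
              noise_sd_g = noise_sd_g, burst_band_hz = burst_band_hz,
              burst_amplitude_g = burst_amplitude_g,
              mean_immobile_s = mean_immobile_s,
              immobility_fraction_target = immobility_fraction_target,
              min_bout_s = min_bout_s, session_s = session_s,
              tail_s = tail_s, first_state = first_state)
  ok <- rate > 0 && pre_start_s > 0 && hang_time_s > 0 && weight_g > 0 &&
    standing_force_fraction > 0 && standing_force_fraction < 1 &&
    noise_sd_g >= 0 && burst_band_hz[1] > 1 && burst_band_hz[2] < 20 &&
    burst_band_hz[1] < burst_band_hz[2] && burst_amplitude_g >= 0 &&
    mean_immobile_s > 0 && immobility_fraction_target > 0 &&
    immobility_fraction_target < 1 && min_bout_s > 0 && session_s > 0 &&
    tail_s >= 0 && first_state %in% c("mobile", "immobile")
  if (!ok) stop("invalid simulation config", call. = FALSE)
  structure(cfg, class = "sim_config")
}

## alternating renewal schedule of bouts tiling [t0, t0 + span)
draw_bout_schedule <- function(t0, span, mean_immobile, frac_target,
                               min_bout, first_state) {
  mean_mobile <- mean_immobile * (1 - frac_target) / frac_target
  state <- first_state
  starts <- numeric(0); states <- character(0)
  t <- t0
  while (t < t0 + span) {
    m <- if (state == "immobile") mean_immobile else mean_mobile
    ## shifted exponential keeps every bout scoreable at video resolution
    d <- min_bout + rexp(1, rate = 1 / max(m - min_bout, 0.1))
    starts <- c(starts, t); states <- c(states, state)
    t <- t + d
    state <- if (state == "immobile") "mobile" else "immobile"
  }
  data.frame(state = states, start_s = starts,
             end_s = c(starts[-1], t0 + span))
}

#' Simulate one load-cell session with ground truth
#'
#' Pre-start: standing force plus noise. At the hang time the force steps
#' to the suspended weight; mobile bouts add amplitude-modulated
#' band-limited struggle bursts on top of the plateau. Bouts follow an
#' alternating renewal schedule. Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#'
#' @return object of class `synthetic_session`: `trace` ([force_trace()]),
#'   `truth_start_s`, `truth_bouts` ([annotation_track()] over
#'   `[start, start + 360)`), `truth_total_immobility_s`, `config`.
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rate <- config$rate
  hang <- config$hang_time_s
  t_begin <- max(hang - config$pre_start_s, 0)
  total_s <- hang + config$session_s + config$tail_s - t_begin
  n <- round(total_s * rate)
  t <- t_begin + (0:(n - 1)) / rate
  post <- t >= hang
  base <- ifelse(post, config$weight_g,
                 config$standing_force_fraction * config$weight_g)
  sched <- draw_bout_schedule(hang, config$session_s + config$tail_s,
                              config$mean_immobile_s,
                              config$immobility_fraction_target,
                              config$min_bout_s, config$first_state)
  mobile_mask <- rep(FALSE, n)
  for (k in which(sched$state == "mobile")) {
    mobile_mask[t >= sched$start_s[k] & t < sched$end_s[k]] <- TRUE
  }
  ## carrier: unit-SD band-limited noise; envelope: rectified slow noise
  carrier <- zero_phase_bandpass(rnorm(n), rate,
                                 band_hz = config$burst_band_hz, order = 4)
  carrier <- carrier / sd(carrier)
  slow <- zero_phase_bandpass(rnorm(n), rate, band_hz = c(0.1, 0.8),
                              order = 4)
  envelope <- config$burst_amplitude_g * abs(slow) / sd(slow)
  burst <- envelope * carrier * mobile_mask
  values <- base + burst + rnorm(n, sd = config$noise_sd_g)
  win_bouts <- clip_schedule(sched, hang, hang + config$session_s)
  truth <- annotation_track(win_bouts, source = "manual", rate = rate)
  structure(
    list(trace = force_trace(t, values, channel_id = 1L,
                             nominal_rate = rate),
         truth_start_s = hang, truth_bouts = truth,
         truth_total_immobility_s = track_immobility_time(truth),
         config = config),
    class = "synthetic_session"
  )
}

clip_schedule <- function(sched, t0, t1) {
  keep <- sched$end_s > t0 & sched$start_s < t1
  out <- sched[keep, , drop = FALSE]
  out$start_s <- pmax(out$start_s, t0)
  out$end_s <- pmin(out$end_s, t1)
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session> seed %d, start %.1f s, immobility %.1f s / %g s\n",
    x$config$seed, x$truth_start_s, x$truth_total_immobility_s,
    x$config$session_s))
  invisible(x)
}

#' Simulate a manual annotation of the truth bouts
#'
#' Emulates a frame-accurate human observer at video resolution: each
#' interior bout boundary is perturbed with Gaussian jitter truncated at
#' just under half the shorter adjacent bout (so bouts never reorder) and
#' snapped to the frame grid. Collisions after snapping are resolved by
#' redrawing (bounded retries).
#'
#' @param truth_bouts the truth [annotation_track()].
#' @param fps video frame rate (default 30).
#' @param onset_jitter_sd_s jitter SD in seconds (default 0.1).
#' @param seed RNG seed.
#' @param max_retries redraw budget for degenerate snaps.
#'
#' @return an [annotation_track()] with `source = "manual"`, `rate = fps`.
#' @export
simulate_manual_annotation <- function(truth_bouts, fps = 30,
                                       onset_jitter_sd_s = 0.1, seed = 1,
                                       max_retries = 100) {
  stopifnot(inherits(truth_bouts, "annotation_track"),
            onset_jitter_sd_s >= 0)
  set.seed(seed)
  b <- truth_bouts$bouts
  nb <- nrow(b)
  if (nb == 1L) {
    return(annotation_track(b, source = "manual", rate = fps,
                            session_span = truth_bouts$session_span))
  }
  durations <- b$end_s - b$start_s
  for (try in seq_len(max_retries)) {
    bnd <- b$end_s[-nb]
    lim <- 0.49 * pmin(durations[-nb], durations[-1])
    jit <- pmin(pmax(rnorm(nb - 1L, sd = onset_jitter_sd_s), -lim), lim)
    snapped <- round((bnd + jit) * fps) / fps
    new_bnd <- pmin(pmax(snapped, b$start_s[1] + 1 / fps),
                    b$end_s[nb] - 1 / fps)
    if (all(diff(c(b$start_s[1], new_bnd, b$end_s[nb])) > 0)) {
      out <- data.frame(state = b$state,
                        start_s = c(b$start_s[1], new_bnd),
                        end_s = c(new_bnd, b$end_s[nb]))
      return(annotation_track(out, source = "manual", rate = fps,
                              session_span = truth_bouts$session_span))
    }
  }
  stop("could not produce a valid annotation within the retry budget",
       call. = FALSE)
}

#' Simulate a cohort with a treatment-like immobility reduction
#'
#' The first half of the cohort is "control", the second half "treated";
#' treated subjects have their immobility-fraction target reduced by
#' `treatment_effect` (absolute reduction, floored at 0.05). Per-subject
#' seeds are derived from `seed` and recorded.
#'
#' @param n cohort size (default 16; >= 2).
#' @param treatment_effect absolute reduction of the immobility fraction
#'   in the treated half (default 0).
#' @param seed master seed.
#' @param config_base a [sim_config()] used as the template.
#' @param fps,onset_jitter_sd_s manual-annotation parameters.
#'
#' @return list of class `synthetic_cohort`; one element per subject with
#'   `subject_id`, `group`, `seed`, `session` (a `synthetic_session`) and
#'   `manual` (an [annotation_track()]).
#' @export
simulate_cohort <- function(n = 16, treatment_effect = 0, seed = 1,
                            config_base = sim_config(), fps = 30,
                            onset_jitter_sd_s = 0.1) {
  stopifnot(n >= 2L)
  set.seed(seed)
  hangs <- runif(n, 60, 180)
  weights <- rnorm(n, 25.47, 1.2)
  subjects <- lapply(seq_len(n), function(i) {
    treated <- i > n / 2
    frac <- config_base$immobility_fraction_target -
      if (treated) treatment_effect else 0
    cfg <- config_base
    cfg$seed <- seed * 1000 + i
    cfg$hang_time_s <- hangs[i]
    cfg$pre_start_s <- hangs[i]
    cfg$weight_g <- weights[i]
    cfg$immobility_fraction_target <- max(frac, 0.05)
    cfg <- do.call(sim_config, unclass(cfg))
    ses <- simulate_session(cfg)
    man <- simulate_manual_annotation(ses$truth_bouts, fps = fps,
                                      onset_jitter_sd_s = onset_jitter_sd_s,
                                      seed = cfg$seed + 500000L)
    list(subject_id = sprintf("M%02d", i),
         group = if (treated) "treated" else "control",
         seed = cfg$seed, session = ses, manual = man)
  })
  structure(subjects, class = "synthetic_cohort")
}

#' Simulate a coupled two-channel photometry session
#'
#' Both channels share a slow multiplicative drift (bleaching trend plus a
#' slow oscillation); exponential-kernel calcium transients (~50 ms rise,
#' ~500 ms decay) are added to the 470 nm channel only, one at every
#' mobility onset plus Poisson-timed extras during mobile bouts; Gaussian
#' sensor noise is added to both channels.
#'
#' @param truth_bouts [annotation_track()] defining the session span and
#'   the mobile bouts.
#' @param rate sampling rate per channel (Hz).
#' @param transient_amp_dff transient amplitude in dF/F units
#'   (0 disables transients).
#' @param transient_rate_hz Poisson rate of extra transients during mobile
#'   bouts.
#' @param noise_sd sensor noise SD (a.u.).
#' @param f0_470,f0_415 baseline fluorescence (a.u.).
#' @param drift_amplitude relative amplitude of the slow shared
#'   oscillation.
#' @param bleach_tau_s time constant of the shared bleaching trend (s).
#' @param seed RNG seed.
#'
#' @return list of class `synthetic_photometry`: `session`
#'   ([photometry_session()]), `transient_times` (s), and the parameters.
#' @export
simulate_photometry <- function(truth_bouts, rate = 40,
                                transient_amp_dff = 0.05,
                                transient_rate_hz = 0.3, noise_sd = 0.05,
                                f0_470 = 200, f0_415 = 150,
                                drift_amplitude = 0.04,
                                bleach_tau_s = 2000, seed = 1) {
  stopifnot(inherits(truth_bouts, "annotation_track"))
  set.seed(seed)
  span <- truth_bouts$session_span
  n <- round((span[2] - span[1]) * rate)
  t <- span[1] + (0:(n - 1)) / rate
  phase <- runif(1, 0, 2 * pi)
  drift <- exp(-(t - span[1]) / bleach_tau_s) *
    (1 + drift_amplitude * sin(2 * pi * (t - span[1]) / 240 + phase))
  mobile <- truth_bouts$bouts[truth_bouts$bouts$state == "mobile", ,
                              drop = FALSE]
  events <- numeric(0)
  if (transient_amp_dff > 0 && nrow(mobile) > 0L) {
    events <- mobile$start_s
    for (k in seq_len(nrow(mobile))) {
      dur <- mobile$end_s[k] - mobile$start_s[k]
      extra <- rpois(1, transient_rate_hz * dur)
      if (extra > 0) {
        events <- c(events, mobile$start_s[k] + runif(extra, 0, dur))
      }
    }
    events <- sort(events)
  }
  s <- rep(0, n)
  if (length(events) > 0L) {
    tau_r <- 0.05; tau_d <- 0.5
    t_pk <- tau_r * log1p(tau_d / tau_r)
    k_pk <- (1 - exp(-t_pk / tau_r)) * exp(-t_pk / tau_d)
    for (te in events) {
      idx <- which(t >= te & t <= te + 5 * tau_d)
      tau <- t[idx] - te
      s[idx] <- s[idx] +
        transient_amp_dff * (1 - exp(-tau / tau_r)) * exp(-tau / tau_d) / k_pk
    }
  }
  sig <- f0_470 * drift * (1 + s) + rnorm(n, sd = noise_sd)
  ctl <- f0_415 * drift + rnorm(n, sd = noise_sd)
  structure(
    list(session = photometry_session(t, sig, ctl, rate = rate),
         transient_times = events,
         params = list(rate = rate, transient_amp_dff = transient_amp_dff,
                       transient_rate_hz = transient_rate_hz,
                       noise_sd = noise_sd, f0_470 = f0_470,
                       f0_415 = f0_415, drift_amplitude = drift_amplitude,
                       bleach_tau_s = bleach_tau_s, seed = seed)),
    class = "synthetic_photometry"
  )
}
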