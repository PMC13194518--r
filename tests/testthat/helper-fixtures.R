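## Small in-code fixtures shared across test files.

## uniform 80 Hz trace from a value vector
make_trace <- function(values, rate = 80, channel = 1L) {
  force_trace((seq_along(values) - 1) / rate, values,
              channel_id = channel, nominal_rate = rate)
}

## step session: standing level until hang, plateau after, optional noise
step_trace <- function(hang = 100, total = 600, rate = 80, lo = 5, hi = 25,
                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- (0:(total * rate - 1)) / rate
  v <- ifelse(t < hang, lo, hi) + rnorm(length(t), sd = noise_sd)
  force_trace(t, v, nominal_rate = rate)
}

## two-state track tiling [t0, t1) from a vector of interior boundaries
simple_track <- function(boundaries, t0 = 0, t1 = 360,
                         first_state = "immobile", rate = 30,
                         source = "manual") {
  states <- rep(c(first_state,
                  setdiff(c("immobile", "mobile"), first_state)),
                length.out = length(boundaries) + 1L)
  annotation_track(
    data.frame(state = states,
               start_s = c(t0, boundaries),
               end_s = c(boundaries, t1)),
    source = source, rate = rate)
}

## filtered_window stand-in with arbitrary values (unit tests only)
make_window <- function(values, rate = 80) {
  structure(list(timestamps = (seq_along(values) - 1) / rate,
                 values = values, rate = rate),
            class = "filtered_window")
}
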