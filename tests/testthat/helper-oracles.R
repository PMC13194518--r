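## Independent brute-force oracles. Each re-derives the quantity from its
## definition with none of the package's vectorized shortcuts, so agreement
## is evidence rather than tautology.

## forward-backward 100-point box convolution with edge-replication padding
oracle_heavy_smooth <- function(v, w = 100) {
  pad <- 2L * w
  vp <- c(rep(v[1], pad), v, rep(v[length(v)], pad))
  causal_box <- function(x) {
    vapply(seq_along(x), function(i) {
      if (i < w) NA_real_ else mean(x[(i - w + 1L):i])
    }, numeric(1))
  }
  fwd <- causal_box(vp)
  bwd <- rev(causal_box(rev(fwd)))
  bwd[(pad + 1L):(pad + length(v))]
}

## exhaustive minimum-SD window scan in the middle third of the post-start
## segment (population SD, earliest window on ties)
oracle_baseline <- function(trace, prov, w = 800) {
  seg <- which(trace$timestamps >= prov)
  third <- floor(length(seg) / 3)
  v <- trace$values[seg[(third + 1L):(2L * third)]]
  sds <- vapply(seq_len(length(v) - w + 1L), function(i) {
    win <- v[i:(i + w - 1L)]
    sqrt(mean((win - mean(win))^2))
  }, numeric(1))
  best <- which.min(sds)
  mean(v[best:(best + w - 1L)])
}

## exhaustive persistence scan: earliest index whose whole forward window
## stays strictly above the threshold
oracle_provisional_start <- function(smoothed, thr, timestamps,
                                     persistence_s) {
  rate <- 1 / median(diff(timestamps))
  m <- as.integer(ceiling(persistence_s * rate))
  for (i in seq_len(length(smoothed) - m + 1L)) {
    if (all(smoothed[i:(i + m - 1L)] > thr)) return(timestamps[i])
  }
  NA_real_
}

## brute-force centered rolling maximum of the rectified signal
oracle_envelope <- function(v, k) {
  a <- abs(v)
  n <- length(a)
  hb <- (k - 1L) %/% 2L
  ha <- k - 1L - hb
  vapply(seq_len(n), function(i) {
    max(a[max(1L, i - hb):min(n, i + ha)])
  }, numeric(1))
}

## topographic prominence by outward scan: walk each side to the first
## strictly higher sample (or the series edge) and take the minimum passed
oracle_peaks <- function(x, min_prominence) {
  n <- length(x)
  out <- data.frame(index = integer(0), prominence = numeric(0))
  for (i in 2:(n - 1L)) {
    if (!(x[i] > x[i - 1L] && x[i] > x[i + 1L])) next
    left <- x[seq_len(i - 1L)]
    higher <- which(left > x[i])
    lmin <- if (length(higher) > 0L) {
      min(left[(max(higher) + 1L):(i - 1L)])
    } else min(left)
    right <- x[(i + 1L):n]
    higher <- which(right > x[i])
    rmin <- if (length(higher) > 0L) {
      min(right[seq_len(min(higher) - 1L)])
    } else min(right)
    prom <- x[i] - max(lmin, rmin)
    if (prom >= min_prominence) {
      out <- rbind(out, data.frame(index = i, prominence = prom))
    }
  }
  out
}

## direct-formula agreement metrics
oracle_f1 <- function(pred, ref) {
  tp <- sum(pred & ref); fp <- sum(pred & !ref); fn <- sum(!pred & ref)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}
oracle_kappa <- function(pred, ref) {
  po <- mean(pred == ref)
  pe <- mean(pred) * mean(ref) + mean(!pred) * mean(!ref)
  if (po == 1) 1 else (po - pe) / (1 - pe)
}
oracle_mae <- function(a, b) sum(abs(a - b)) / length(a)

## nearest-native-sample lookup, earlier sample on exact ties
oracle_resample <- function(track, grid) {
  rate <- track$rate
  t0 <- track$session_span[1]
  native <- t0 + (seq_len(round((track$session_span[2] - t0) * rate)) - 1) / rate
  vapply(grid, function(tg) {
    d <- abs(native - tg)
    tn <- native[which(d <= min(d) + 1e-8)[1]]
    b <- track$bouts
    idx <- max(which(b$start_s <= tn + 1e-12))
    b$state[min(idx, nrow(b))] == "immobile"
  }, logical(1))
}
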