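## Agreement between binary scoring tracks sampled at different rates.
## Tracks are resampled onto a common grid (the smallest native time step)
## by nearest-neighbor assignment, preserving the binary structure, and then
## compared with confusion counts, precision/recall/F1 and Cohen's kappa,
## with "immobile" as the positive class throughout.

state_at <- function(track, times) {
  starts <- track$bouts$start_s
  idx <- findInterval(times, starts)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(track$bouts)] <- nrow(track$bouts)
  track$bouts$state[idx] == "immobile"
}

#' Resample annotation tracks onto a common temporal grid
#'
#' The grid step is the smallest native step among the tracks; tracks are
#' truncated to the overlapping span first (spans may disagree by at most
#' one native step). Each grid point takes the state of the nearest native
#' sample of each track, the earlier sample winning exact ties, so outputs
#' stay strictly binary.
#'
#' @param tracks list of two or more [annotation_track()]s (named lists
#'   keep their names).
#' @param span_tol maximum allowed disagreement between session spans in
#'   seconds before the tracks are declared unaligned. Defaults to one
#'   native step of the coarsest track; widen (e.g. to the start-detection
#'   accuracy, 0.5 s) when comparing tracks anchored at independently
#'   detected starts.
#'
#' @return list with `series` (named list of logical vectors, `TRUE` =
#'   immobile), `grid_times` (absolute seconds) and `grid_step` (s).
#' @export
resample_to_grid <- function(tracks, span_tol = NULL) {
  stopifnot(is.list(tracks), length(tracks) >= 2L)
  lapply(tracks, function(tr) stopifnot(inherits(tr, "annotation_track")))
  spans <- vapply(tracks, function(tr) tr$session_span, numeric(2))
  steps <- vapply(tracks, function(tr) 1 / tr$rate, numeric(1))
  if (is.null(span_tol)) span_tol <- max(steps)
  t0 <- max(spans[1, ])
  t1 <- min(spans[2, ])
  if (max(spans[1, ]) - min(spans[1, ]) > span_tol + 1e-9 ||
      max(spans[2, ]) - min(spans[2, ]) > span_tol + 1e-9) {
    stop("unaligned session spans", call. = FALSE)
  }
  if (t1 <= t0) stop("unaligned session spans", call. = FALSE)
  grid_step <- min(steps)
  m <- floor((t1 - t0) / grid_step + 1e-9)
  grid <- t0 + (seq_len(m) - 1L) * grid_step
  series <- lapply(tracks, function(tr) {
    rate <- tr$rate
    tt0 <- tr$session_span[1]
    n_native <- round((tr$session_span[2] - tt0) * rate)
    ## nearest native sample; an exact (to 1e-9) half-step tie resolves to
    ## the earlier sample
    idx <- (grid - tt0) * rate
    k <- floor(idx)
    k <- k + as.integer(idx - k > 0.5 + 1e-9)
    k[k < 0] <- 0
    k[k > n_native - 1L] <- n_native - 1L
    state_at(tr, tt0 + k / rate)
  })
  names(series) <- names(tracks)
  list(series = series, grid_times = grid, grid_step = grid_step)
}

#' Confusion counts between two binary series
#'
#' @param pred,ref logical (or 0/1) vectors of equal length; `TRUE` =
#'   immobile, the positive class.
#' @return named integer vector `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, ref) {
  pred <- as.logical(pred); ref <- as.logical(ref)
  if (length(pred) != length(ref)) stop("unaligned series", call. = FALSE)
  c(TP = sum(pred & ref), FP = sum(pred & !ref),
    FN = sum(!pred & ref), TN = sum(!pred & !ref))
}

#' F1 score from confusion counts
#'
#' Harmonic mean of precision and recall; 0 when there are no true
#' positives. Undefined precision or recall (zero denominator) maps to 0
#' with a warning.
#'
#' @param TP,FP,FN non-negative counts.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(TP, FP, FN) {
  TP <- unname(TP); FP <- unname(FP); FN <- unname(FN)
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP + FP + FN == 0) stop("empty comparison", call. = FALSE)
  if (TP == 0) {
    if (TP + FP == 0 || TP + FN == 0) {
      warning("precision or recall undefined (no predicted/actual positives); returning 0")
    }
    return(0)
  }
  p <- TP / (TP + FP)
  r <- TP / (TP + FN)
  2 * p * r / (p + r)
}

#' Cohen's kappa between two binary series
#'
#' `kappa = (Po - Pe) / (1 - Pe)` with `Po` the observed agreement and
#' `Pe` the chance agreement from the marginal class frequencies. Perfect
#' agreement returns 1, including the degenerate case `Pe = 1` (both
#' raters constant and equal).
#'
#' @param pred,ref logical (or 0/1) vectors of equal length, at least 2.
#' @return kappa coefficient (<= 1).
#' @export
kappa_score <- function(pred, ref) {
  pred <- as.logical(pred); ref <- as.logical(ref)
  if (length(pred) != length(ref)) stop("unaligned series", call. = FALSE)
  stopifnot(length(pred) >= 2L)
  po <- mean(pred == ref)
  if (po == 1) return(1)
  p1 <- mean(pred); p2 <- mean(ref)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  (po - pe) / (1 - pe)
}

#' Agreement report between a candidate and a reference series
#'
#' @param pred,ref aligned logical series (`TRUE` = immobile).
#' @param grid_step grid step in seconds (recorded in the report).
#' @return list of class `agreement_report`: counts `TP/FP/FN/TN`,
#'   `precision`, `recall`, `f1`, `kappa`, `po`, `pe`, `grid_step`.
#' @export
agreement_report <- function(pred, ref, grid_step = NA_real_) {
  cc <- confusion(pred, ref)
  precision <- if (cc["TP"] + cc["FP"] == 0) {
    warning("precision undefined; returning 0"); 0
  } else unname(cc["TP"] / (cc["TP"] + cc["FP"]))
  recall <- if (cc["TP"] + cc["FN"] == 0) {
    warning("recall undefined; returning 0"); 0
  } else unname(cc["TP"] / (cc["TP"] + cc["FN"]))
  po <- mean(as.logical(pred) == as.logical(ref))
  p1 <- mean(as.logical(pred)); p2 <- mean(as.logical(ref))
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  structure(
    list(TP = unname(cc["TP"]), FP = unname(cc["FP"]),
         FN = unname(cc["FN"]), TN = unname(cc["TN"]),
         precision = precision, recall = recall,
         f1 = suppressWarnings(f1_score(cc["TP"], cc["FP"], cc["FN"])),
         kappa = kappa_score(pred, ref), po = po, pe = pe,
         grid_step = grid_step),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> F1 %.3f, kappa %.3f (Po %.3f, Pe %.3f), P %.3f, R %.3f\n",
    x$f1, x$kappa, x$po, x$pe, x$precision, x$recall))
  invisible(x)
}

#' Compare candidate scoring tracks against a manual reference
#'
#' Resamples the reference and all candidates onto their common grid and
#' reports per-candidate agreement (F1, kappa, precision, recall, Po, Pe)
#' plus the absolute error of total immobility time, in the order the
#' candidates are given.
#'
#' @param reference the reference [annotation_track()] (manual scoring).
#' @param candidates named list of candidate [annotation_track()]s.
#' @param span_tol span-alignment tolerance passed to
#'   [resample_to_grid()].
#'
#' @return data frame with one row per candidate: `candidate`, `f1`,
#'   `kappa`, `precision`, `recall`, `po`, `pe`, `mae_s`, `grid_hz`.
#' @export
compare_methods <- function(reference, candidates, span_tol = NULL) {
  stopifnot(inherits(reference, "annotation_track"),
            is.list(candidates), length(candidates) >= 1L)
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate", seq_along(candidates))
  }
  all_tracks <- c(list(.reference = reference), candidates)
  g <- resample_to_grid(all_tracks, span_tol = span_tol)
  ref_series <- g$series[[".reference"]]
  ref_total <- track_immobility_time(reference)
  rows <- lapply(names(candidates), function(nm) {
    rep <- agreement_report(g$series[[nm]], ref_series,
                            grid_step = g$grid_step)
    data.frame(candidate = nm, f1 = rep$f1, kappa = rep$kappa,
               precision = rep$precision, recall = rep$recall,
               po = rep$po, pe = rep$pe,
               mae_s = abs(track_immobility_time(candidates[[nm]]) -
                             ref_total),
               grid_hz = 1 / g$grid_step)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
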