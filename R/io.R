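## External formats and the core data containers.
##
## Time convention: seconds, 0-based at recording start; bout intervals are
## half-open [start, end). Force is held in grams everywhere inside the
## package; log readers convert once at the boundary. Delimited text is
## comma-separated with a "." decimal and one header row.

#' Construct a load-cell force trace
#'
#' A `force_trace` holds timestamped, calibrated force samples from one
#' load-cell channel, in grams.
#'
#' @param timestamps numeric vector of seconds from recording start,
#'   strictly increasing.
#' @param values numeric vector of force in grams, same length.
#' @param channel_id integer channel number (1--4).
#' @param nominal_rate nominal sampling rate in Hz (default 80). The median
#'   sampling interval must lie within 20% of `1/nominal_rate`.
#'
#' @return An object of class `force_trace` with fields `timestamps`,
#'   `values`, `channel_id`, `nominal_rate`.
#' @export
force_trace <- function(timestamps, values, channel_id = 1L,
                        nominal_rate = 80) {
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    stop("timestamps and values must have equal length", call. = FALSE)
  }
  if (length(timestamps) < 2L) stop("empty log", call. = FALSE)
  if (any(diff(timestamps) <= 0)) stop("corrupt timebase", call. = FALSE)
  if (!is.numeric(nominal_rate) || nominal_rate <= 0) {
    stop("nominal_rate must be positive", call. = FALSE)
  }
  med_dt <- median(diff(timestamps))
  if (abs(med_dt - 1 / nominal_rate) > 0.2 / nominal_rate) {
    stop("median sampling interval inconsistent with nominal_rate",
         call. = FALSE)
  }
  channel_id <- as.integer(channel_id)
  if (is.na(channel_id) || channel_id < 1L || channel_id > 4L) {
    stop("channel_id must be in 1..4", call. = FALSE)
  }
  structure(
    list(timestamps = timestamps, values = values,
         channel_id = channel_id, nominal_rate = nominal_rate),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf(
    "<force_trace> channel %d, %d samples, %.1f s at %g Hz, %.2f-%.2f g\n",
    x$channel_id, length(x$values),
    x$timestamps[length(x$timestamps)] - x$timestamps[1],
    x$nominal_rate, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.force_trace <- function(x, ...) {
  plot(x$timestamps, x$values, type = "l", xlab = "time (s)",
       ylab = "force (g)", ...)
  invisible(x)
}

#' Construct a video frame-to-time map
#'
#' @param frame_indices 0-based integer frame indices, strictly increasing
#'   from 0.
#' @param timestamps non-decreasing timestamps in seconds.
#'
#' @return An object of class `frame_time_map`.
#' @export
frame_time_map <- function(frame_indices, timestamps) {
  frame_indices <- as.integer(frame_indices)
  timestamps <- as.numeric(timestamps)
  stopifnot(length(frame_indices) == length(timestamps))
  if (length(frame_indices) == 0L || frame_indices[1] != 0L ||
      any(diff(frame_indices) <= 0L)) {
    stop("frame_indices must increase strictly from 0", call. = FALSE)
  }
  if (any(diff(timestamps) < 0)) {
    stop("frame timestamps must be non-decreasing", call. = FALSE)
  }
  structure(list(frame_indices = frame_indices, timestamps = timestamps),
            class = "frame_time_map")
}

#' Convert frame indices to seconds through a frame-time map
#'
#' Frames present in the map use the recorded timestamp; others are linearly
#' interpolated (and extrapolated at the nominal frame rate beyond the map).
#'
#' @param map a [frame_time_map()].
#' @param frames numeric vector of 0-based frame indices.
#' @return numeric vector of seconds.
#' @export
frames_to_seconds <- function(map, frames) {
  stopifnot(inherits(map, "frame_time_map"))
  approx(map$frame_indices, map$timestamps, xout = frames, rule = 2)$y +
    ifelse(frames > max(map$frame_indices),
           (frames - max(map$frame_indices)) *
             median(diff(map$timestamps)), 0)
}

#' Construct a behavioral annotation track
#'
#' Bouts of alternating `immobile`/`mobile` state that tile the session span
#' with half-open `[start_s, end_s)` intervals.
#'
#' @param bouts data frame with columns `state` (`"immobile"` or
#'   `"mobile"`), `start_s`, `end_s`.
#' @param source `"manual"` (video-derived) or `"automated"`
#'   (sensor-derived).
#' @param rate native sampling rate in Hz (30 for video, 80 for sensor).
#' @param session_span length-2 numeric `(t0, t1)`; defaults to the span of
#'   the bouts.
#' @param tol numeric tolerance for the tiling checks.
#'
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(bouts, source = c("manual", "automated"),
                             rate = 30, session_span = NULL, tol = 1e-9) {
  source <- match.arg(source)
  stopifnot(is.data.frame(bouts),
            all(c("state", "start_s", "end_s") %in% names(bouts)))
  bouts <- data.frame(state = as.character(bouts$state),
                      start_s = as.numeric(bouts$start_s),
                      end_s = as.numeric(bouts$end_s))
  if (nrow(bouts) == 0L) stop("annotation has no bouts", call. = FALSE)
  if (!all(bouts$state %in% c("immobile", "mobile"))) {
    stop("states must be 'immobile' or 'mobile'", call. = FALSE)
  }
  ord <- order(bouts$start_s)
  bouts <- bouts[ord, , drop = FALSE]
  rownames(bouts) <- NULL
  if (any(bouts$end_s - bouts$start_s <= 0)) {
    stop("all bout durations must be > 0", call. = FALSE)
  }
  if (nrow(bouts) > 1L) {
    gaps <- bouts$start_s[-1] - bouts$end_s[-nrow(bouts)]
    if (any(gaps < -tol)) stop("overlapping annotation", call. = FALSE)
    if (any(gaps > tol)) stop("non-tiling annotation", call. = FALSE)
    if (any(bouts$state[-1] == bouts$state[-nrow(bouts)])) {
      stop("adjacent bouts must alternate states", call. = FALSE)
    }
  }
  if (is.null(session_span)) {
    session_span <- c(bouts$start_s[1], bouts$end_s[nrow(bouts)])
  } else {
    session_span <- as.numeric(session_span)
    if (abs(bouts$start_s[1] - session_span[1]) > tol ||
        abs(bouts$end_s[nrow(bouts)] - session_span[2]) > tol) {
      stop("non-tiling annotation", call. = FALSE)
    }
  }
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  structure(
    list(bouts = bouts, source = source, rate = rate,
         session_span = session_span),
    class = "annotation_track"
  )
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf(
    "<annotation_track> %s at %g Hz, %d bouts on [%.3f, %.3f) s, immobility %.1f s\n",
    x$source, x$rate, nrow(x$bouts), x$session_span[1], x$session_span[2],
    track_immobility_time(x)))
  invisible(x)
}

#' Total immobility time of an annotation track
#'
#' @param track an [annotation_track()].
#' @return total immobile bout duration in seconds.
#' @export
track_immobility_time <- function(track) {
  stopifnot(inherits(track, "annotation_track"))
  im <- track$bouts$state == "immobile"
  sum(track$bouts$end_s[im] - track$bouts$start_s[im])
}

## ---------------------------------------------------------------- readers

read_delim_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Read a load-cell force log
#'
#' Expects a CSV with columns `time_s, ch1..chN` (N <= 4) and an optional
#' second "units" row (first field literally `units`, then one unit per
#' channel, `mg` or `g`). Milligram-scale values are converted to grams;
#' without a units row the values are taken to be grams already.
#' Timestamps are normalized to start at the file's first timestamp.
#'
#' @param path path to the log file.
#' @param channel integer channel to extract (column `ch<channel>`).
#' @param nominal_rate nominal sampling rate in Hz.
#'
#' @return A [force_trace()].
#' @export
read_force_log <- function(path, channel = 1L, nominal_rate = 80) {
  stopifnot(file.exists(path))
  header <- strsplit(readLines(path, n = 2L), ",")[[1]]
  second <- readLines(path, n = 2L)
  has_units <- length(second) >= 2L && startsWith(second[2], "units")
  units <- NULL
  if (has_units) {
    units_row <- strsplit(second[2], ",")[[1]]
    units <- units_row[-1]
    df <- read.csv(path, skip = 2L, header = FALSE,
                   col.names = header, stringsAsFactors = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  col <- paste0("ch", as.integer(channel))
  if (!col %in% names(df)) stop("channel not found", call. = FALSE)
  if (!"time_s" %in% names(df)) stop("time_s column missing", call. = FALSE)
  if (nrow(df) < 2L) stop("empty log", call. = FALSE)
  tvec <- as.numeric(df$time_s)
  if (any(diff(tvec) <= 0)) stop("corrupt timebase", call. = FALSE)
  vals <- as.numeric(df[[col]])
  if (has_units) {
    chan_units <- units[match(col, setdiff(header, "time_s"))]
    if (!is.na(chan_units) && chan_units == "mg") vals <- vals / 1000
  }
  force_trace(tvec - tvec[1], vals, channel_id = channel,
              nominal_rate = nominal_rate)
}

#' Write a load-cell force log
#'
#' Inverse of [read_force_log()]; writes `time_s,ch<k>` plus a units row.
#'
#' @param trace a [force_trace()].
#' @param path output path.
#' @param units `"mg"` (values multiplied by 1000 on disk) or `"g"`.
#' @return `path`, invisibly.
#' @export
write_force_log <- function(trace, path, units = c("mg", "g")) {
  stopifnot(inherits(trace, "force_trace"))
  units <- match.arg(units)
  vals <- if (units == "mg") trace$values * 1000 else trace$values
  col <- paste0("ch", trace$channel_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("time_s,", col), paste0("units,", units)), con)
  write.table(
    data.frame(time_s = trace$timestamps, v = format(vals, digits = 15)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a frame-time map
#'
#' CSV with columns `frame`, `time_s`.
#'
#' @param path path to the file.
#' @return A [frame_time_map()].
#' @export
read_frame_time_map <- function(path) {
  df <- read_delim_table(path)
  stopifnot(all(c("frame", "time_s") %in% names(df)))
  frame_time_map(df$frame, df$time_s)
}

#' Read a behavioral annotation file
#'
#' Accepts CSV or XLSX with columns `state, start_s, end_s` (seconds) or
#' `state, start_frame, end_frame` together with a frame-time map. A
#' `subject` column, if present, is filtered with the `subject` argument.
#'
#' @param path path to the annotation file.
#' @param frame_map a [frame_time_map()], required for frame-based files.
#' @param subject optional subject id to select when the file holds several.
#' @param source annotation provenance, `"manual"` or `"automated"`.
#' @param rate native rate of the annotations in Hz.
#'
#' @return An [annotation_track()].
#' @export
read_annotation <- function(path, frame_map = NULL, subject = NULL,
                            source = "manual", rate = 30) {
  df <- read_delim_table(path)
  if (!is.null(subject) && "subject" %in% names(df)) {
    df <- df[df$subject == subject, , drop = FALSE]
  }
  if (all(c("start_s", "end_s") %in% names(df))) {
    bouts <- data.frame(state = df$state, start_s = df$start_s,
                        end_s = df$end_s)
  } else if (all(c("start_frame", "end_frame") %in% names(df))) {
    if (is.null(frame_map)) {
      stop("frame-based annotation requires a frame_map", call. = FALSE)
    }
    bouts <- data.frame(
      state = df$state,
      start_s = frames_to_seconds(frame_map, df$start_frame),
      end_s = frames_to_seconds(frame_map, df$end_frame))
  } else {
    stop("annotation must have start_s/end_s or start_frame/end_frame",
         call. = FALSE)
  }
  annotation_track(bouts, source = source, rate = rate)
}

#' Write a behavioral annotation file
#'
#' @param track an [annotation_track()].
#' @param path output CSV path.
#' @param subject subject id written into the `subject` column.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(track, path, subject = "s1") {
  stopifnot(inherits(track, "annotation_track"))
  df <- data.frame(subject = subject, state = track$bouts$state,
                   start_s = track$bouts$start_s,
                   end_s = track$bouts$end_s)
  write.csv(format(df, digits = 15, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write a per-subject score report
#'
#' One row per subject: id, total immobility (s), latency (s), per-minute
#' immobility (6 columns), and the threshold used, in that fixed order.
#'
#' @param summaries list of `score_summary` objects (see
#'   [summarize_bouts()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(summaries, path) {
  if (length(summaries) == 0L) stop("nothing to write", call. = FALSE)
  if (inherits(summaries, "score_summary")) summaries <- list(summaries)
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "score_summary"))
    out <- data.frame(subject = s$subject_id,
                      total_immobility_s = s$total_immobility,
                      latency_s = s$latency)
    pm <- as.list(s$per_minute)
    names(pm) <- paste0("min", seq_along(pm), "_s")
    cbind(out, as.data.frame(pm),
          data.frame(threshold_g = s$threshold_used))
  })
  df <- do.call(rbind, rows)
  write.csv(format(df, digits = 15, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a score report written by [write_score_report()]
#'
#' @param path path to the CSV report.
#' @return data frame with one row per subject.
#' @export
read_score_report <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
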