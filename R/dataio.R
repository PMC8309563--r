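#' Euclidean norm of triaxial acceleration
#'
#' Computes the norm channel `An = sqrt(Ax^2 + Ay^2 + Az^2)` sample by
#' sample. The norm is orientation-invariant, which makes it a useful fourth
#' channel alongside the raw axes.
#'
#' @param ax,ay,az numeric vectors of equal length, acceleration in g.
#' @return numeric vector of Euclidean norms (non-negative).
#' @export
#' @examples
#' compute_norm(3, 4, 0) # 5
compute_norm <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ax) != length(az)) {
    stop("ax, ay, az must have equal length")
  }
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az))) {
    stop("compute_norm requires finite inputs")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Construct a labeled accelerometer recording
#'
#' A recording holds one subject/trial multichannel stream: millisecond
#' timestamps, the three acceleration axes, the norm channel and a
#' per-sample activity label.
#'
#' @param subject_id integer subject identifier.
#' @param trial_no integer trial number (1..6 in the protocol).
#' @param timestamp_ms strictly increasing numeric timestamps in
#'   milliseconds since trial start.
#' @param ax,ay,az acceleration channels in g, same length as
#'   `timestamp_ms`.
#' @param an norm channel; computed via [compute_norm()] when `NULL`.
#' @param label per-sample activity labels, same length; defaults to
#'   `"transition"` everywhere.
#' @param participant_ref character reference string for the participant.
#' @param fs nominal sampling rate in Hz (metadata).
#' @return an object of class `har_recording`.
#' @export
recording <- function(subject_id, trial_no, timestamp_ms, ax, ay, az,
                      an = NULL, label = NULL,
                      participant_ref = sprintf("P%02d_SYN", subject_id),
                      fs = 64) {
  n <- length(timestamp_ms)
  if (length(ax) != n || length(ay) != n || length(az) != n) {
    stop("all channel sequences must have equal length")
  }
  if (n > 1 && any(diff(timestamp_ms) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (is.null(an)) an <- compute_norm(ax, ay, az)
  if (length(an) != n) stop("an must match channel length")
  if (is.null(label)) label <- rep(transition_label(), n)
  if (length(label) != n) stop("label must match channel length")
  structure(
    list(subject_id = as.integer(subject_id), trial_no = as.integer(trial_no),
         participant_ref = participant_ref,
         timestamp_ms = as.numeric(timestamp_ms),
         ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         an = as.numeric(an), label = as.character(label), fs = fs),
    class = "har_recording")
}

#' @export
print.har_recording <- function(x, ...) {
  cat(sprintf("<har_recording> subject %d trial %d: %d samples @ %g Hz\n",
              x$subject_id, x$trial_no, length(x$timestamp_ms), x$fs))
  tab <- table(x$label)
  cat("  labels:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
length.har_recording <- function(x) length(x$timestamp_ms)

rec_schema <- c("Index", "Participant number", "Participant reference",
                "Trial number", "Timestamp", "Ax", "Ay", "Az", "An",
                "activity name")

#' Write a recording to CSV
#'
#' Serializes a recording in the fixed ten-column schema: Index, Participant
#' number, Participant reference, Trial number, Timestamp, Ax, Ay, Az, An,
#' activity name. Timestamps are written as milliseconds since trial start
#' (3 decimals, exact at 64 Hz); accelerations at 8 significant digits.
#'
#' @param rec a `har_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "har_recording"))
  n <- length(rec$timestamp_ms)
  df <- data.frame(
    Index = seq_len(n),
    pn = rep(rec$subject_id, n),
    pr = rep(rec$participant_ref, n),
    tn = rep(rec$trial_no, n),
    ts = sprintf("%.3f", rec$timestamp_ms),
    Ax = sprintf("%.8g", rec$ax),
    Ay = sprintf("%.8g", rec$ay),
    Az = sprintf("%.8g", rec$az),
    An = sprintf("%.8g", rec$an),
    an_name = rec$label,
    stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- rec_schema
  write.csv(df, path, row.names = FALSE, quote = c(3, 10))
  invisible(path)
}

# Accepts either numeric milliseconds or a wall-clock string
# "YYYY-mm-dd HH:MM:SS.FFF"; wall-clock times are normalized to
# milliseconds since the first sample.
parse_timestamps <- function(ts) {
  num <- suppressWarnings(as.numeric(ts))
  if (!anyNA(num)) return(num)
  t0 <- as.POSIXct(ts, format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  if (anyNA(t0)) stop("unparseable Timestamp column")
  round(as.numeric(t0 - t0[1], units = "secs") * 1000, 3)
}

#' Read a recording from CSV
#'
#' Reads the ten-column schema written by [write_recording()]. Wall-clock
#' timestamps are accepted and normalized to milliseconds since trial
#' start. A missing `An` column is filled via [compute_norm()]; an `An`
#' column inconsistent with the norm of (Ax, Ay, Az) beyond `tol` triggers a
#' warning and is recomputed.
#'
#' @param path CSV file path.
#' @param tol absolute tolerance for the `An` consistency check.
#' @return a `har_recording`.
#' @export
read_recording <- function(path, tol = 1e-4) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- setdiff(rec_schema, "An")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  ts <- parse_timestamps(df[["Timestamp"]])
  if (length(ts) > 1 && any(diff(ts) <= 0)) {
    stop("non-monotone timestamps")
  }
  ax <- as.numeric(df[["Ax"]]); ay <- as.numeric(df[["Ay"]])
  az <- as.numeric(df[["Az"]])
  an_ref <- compute_norm(ax, ay, az)
  if (!"An" %in% names(df)) {
    an <- an_ref
  } else {
    an <- as.numeric(df[["An"]])
    if (max(abs(an - an_ref)) > tol) {
      warning("An column inconsistent with the norm of (Ax, Ay, Az); recomputed")
      an <- an_ref
    }
  }
  recording(subject_id = df[["Participant number"]][1],
            trial_no = df[["Trial number"]][1],
            timestamp_ms = ts, ax = ax, ay = ay, az = az, an = an,
            label = as.character(df[["activity name"]]),
            participant_ref = as.character(df[["Participant reference"]][1]))
}

#' Apply ground-truth label intervals to a recording
#'
#' Each sample whose timestamp falls in the half-open interval
#' `[start, end)` of an entry gets that entry's label; samples outside every
#' interval are labeled `"transition"`. The half-open convention prevents
#' double labeling at activity boundaries.
#'
#' @param rec a `har_recording`.
#' @param intervals data frame with columns `start`, `end` (milliseconds)
#'   and `label`; intervals must be non-overlapping.
#' @return the recording with its `label` field replaced.
#' @export
apply_labels <- function(rec, intervals) {
  stopifnot(inherits(rec, "har_recording"))
  if (nrow(intervals) == 0) {
    rec$label <- rep(transition_label(), length(rec$timestamp_ms))
    return(rec)
  }
  if (any(intervals$start >= intervals$end)) {
    stop("each interval must have start < end")
  }
  o <- order(intervals$start)
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1 &&
      any(intervals$start[-1] < intervals$end[-nrow(intervals)])) {
    stop("overlapping intervals")
  }
  lab <- rep(transition_label(), length(rec$timestamp_ms))
  for (i in seq_len(nrow(intervals))) {
    sel <- rec$timestamp_ms >= intervals$start[i] &
      rec$timestamp_ms < intervals$end[i]
    lab[sel] <- intervals$label[i]
  }
  rec$label <- lab
  rec
}
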