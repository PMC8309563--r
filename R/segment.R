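# LOSO fold planning and fixed-size overlapping sliding-window (FOSW)
# segmentation.

#' Plan leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set is that subject, the training
#' set is every other subject. Folds are ordered by ascending test subject
#' id, which makes the plan deterministic.
#'
#' @param subject_ids integer vector (or set) of subject ids; at least 2
#'   distinct ids.
#' @return object of class `fold_plan`: a list of folds, each a list with
#'   `train` (integer vector) and `test` (single id).
#' @export
#' @examples
#' make_fold_plan(c(3, 1, 2))
make_fold_plan <- function(subject_ids) {
  ids <- sort(unique(as.integer(subject_ids)))
  if (length(ids) < 2) {
    stop("leave-one-subject-out needs at least 2 subjects")
  }
  folds <- lapply(ids, function(s) list(train = setdiff(ids, s), test = s))
  structure(folds, class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d leave-one-subject-out folds (test subjects: %s)\n",
              length(x), paste(vapply(x, `[[`, integer(1), "test"),
                               collapse = ", ")))
  invisible(x)
}

empty_segments <- function(T_len, channels = c("Ax", "Ay", "Az", "An")) {
  structure(
    list(values = array(numeric(0), dim = c(0, T_len, length(channels)),
                        dimnames = list(NULL, NULL, channels)),
         labels = character(0), subject_ids = integer(0),
         trial_ids = integer(0)),
    class = "segment_tensor")
}

#' Segment a recording into a windowed tensor
#'
#' Applies a fixed-size overlapping sliding window of `window_seconds`
#' seconds with the given overlap fraction to the four channels
#' (Ax, Ay, Az, An). Window starts advance by
#' `stride = round(T * (1 - overlap))` samples. A window is kept only if it
#' is pure — all `T` sample labels identical — and its label is not in
#' `drop_labels` (transitional stretches by default). Values are copies of
#' the stream, stored in a K x T x 4 tensor with one label per window.
#'
#' @param rec a `har_recording`.
#' @param window_seconds window length in seconds (default 1 s).
#' @param overlap overlap fraction in `[0, 1)` (default 0.5).
#' @param fs sampling rate in Hz; defaults to the recording's rate.
#' @param drop_labels labels whose windows are discarded.
#' @return object of class `segment_tensor` with fields `values`
#'   (K x T x 4 array), `labels`, `subject_ids`, `trial_ids`. A stream
#'   shorter than one window yields K = 0.
#' @export
segment_recording <- function(rec, window_seconds = 1, overlap = 0.5,
                              fs = rec$fs,
                              drop_labels = transition_label()) {
  stopifnot(inherits(rec, "har_recording"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  T_len <- round(fs * window_seconds)
  if (T_len < 1) stop("window shorter than one sample")
  n <- length(rec$timestamp_ms)
  if (n < T_len) return(empty_segments(T_len))
  stride <- max(1L, as.integer(round(T_len * (1 - overlap))))
  starts <- seq.int(0L, n - T_len, by = stride) # 0-based window starts
  # purity: all T labels within the window identical
  keep <- logical(length(starts))
  lab <- character(length(starts))
  for (i in seq_along(starts)) {
    w <- rec$label[(starts[i] + 1L):(starts[i] + T_len)]
    if (all(w == w[1L])) {
      keep[i] <- !(w[1L] %in% drop_labels)
      lab[i] <- w[1L]
    }
  }
  starts <- starts[keep]
  lab <- lab[keep]
  k <- length(starts)
  if (k == 0) return(empty_segments(T_len))
  values <- array(NA_real_, dim = c(k, T_len, 4),
                  dimnames = list(NULL, NULL, c("Ax", "Ay", "Az", "An")))
  chans <- list(rec$ax, rec$ay, rec$az, rec$an)
  idx <- outer(starts, seq_len(T_len), `+`) # k x T sample indices
  for (c in 1:4) {
    values[, , c] <- matrix(chans[[c]][idx], k, T_len)
  }
  structure(
    list(values = values, labels = lab,
         subject_ids = rep(rec$subject_id, k),
         trial_ids = rep(rec$trial_no, k)),
    class = "segment_tensor")
}

#' Combine segment tensors
#'
#' Row-binds tensors produced by [segment_recording()] (same window length
#' and channel count required).
#'
#' @param ... `segment_tensor` objects, or a single list of them.
#' @return a `segment_tensor`.
#' @export
bind_segments <- function(...) {
  segs <- list(...)
  if (length(segs) == 1 && !inherits(segs[[1]], "segment_tensor")) {
    segs <- segs[[1]]
  }
  stopifnot(all(vapply(segs, inherits, logical(1), "segment_tensor")))
  dims <- vapply(segs, function(s) dim(s$values)[2:3], numeric(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1])) {
    stop("segment tensors have mismatched window length or channels")
  }
  T_len <- dim(segs[[1]]$values)[2]
  values <- do.call(rbind, lapply(segs, function(s) {
    matrix(s$values, nrow = dim(s$values)[1])
  }))
  k <- nrow(values)
  structure(
    list(values = array(values, dim = c(k, T_len, 4),
                        dimnames = dimnames(segs[[1]]$values)),
         labels = unlist(lapply(segs, `[[`, "labels"), use.names = FALSE),
         subject_ids = unlist(lapply(segs, `[[`, "subject_ids"),
                              use.names = FALSE),
         trial_ids = unlist(lapply(segs, `[[`, "trial_ids"),
                            use.names = FALSE)),
    class = "segment_tensor")
}

#' @export
print.segment_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<segment_tensor> K=%d windows x T=%d samples x m=%d channels\n",
              d[1], d[2], d[3]))
  if (d[1] > 0) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s(%d)", names(tab), tab),
                           collapse = " "), "\n")
  }
  invisible(x)
}

# Subset windows of a tensor by index.
subset_segments <- function(seg, idx) {
  structure(
    list(values = seg$values[idx, , , drop = FALSE],
         labels = seg$labels[idx],
         subject_ids = seg$subject_ids[idx],
         trial_ids = seg$trial_ids[idx]),
    class = "segment_tensor")
}
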