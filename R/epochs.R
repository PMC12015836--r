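# Canonical in-memory data model.
#
# ContinuousRecording: channels x samples matrix in microvolts with a marker
# table. EpochSet: trials x channels x samples array with a time vector in
# ms, condition tag and a non-destructive per-trial rejection mask.
#
# Time convention: an epoch window [t_start, t_end) is half-open in ms; at
# 500 Hz the study window -200..1000 ms gives 600 samples, sample k (1-based)
# has time t_start + (k-1) * 1000/fs, and stimulus onset t = 0 falls on a
# sample. Analysis windows (e.g. 350-410 ms) are closed on both ends with
# nearest-sample rounding (see window_samples()).

#' Construct a continuous multi-channel recording
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param markers Data frame with columns `sample` (1-based sample index)
#'   and `label`, or `NULL` for none.
#' @return An object of class `ContinuousRecording`.
#' @export
continuous_recording <- function(data, sampling_rate, channel_labels,
                                 markers = NULL) {
  data <- as.matrix(data)
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", nrow(data), ")")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (is.null(markers))
    markers <- data.frame(sample = integer(0), label = character(0))
  markers <- as.data.frame(markers)
  stopifnot(all(c("sample", "label") %in% names(markers)))
  if (nrow(markers) &&
      (any(markers$sample < 1) || any(markers$sample > ncol(data))))
    stop("marker sample indices fall outside the recording")
  rownames(data) <- channel_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = channel_labels, markers = markers),
            class = "ContinuousRecording")
}

#' @export
print.ContinuousRecording <- function(x, ...) {
  cat("<ContinuousRecording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sampling_rate, " Hz, ", nrow(x$markers),
      " markers\n", sep = "")
  invisible(x)
}

#' Construct an epoched data set
#'
#' @param data trials x channels x samples numeric array (microvolts).
#' @param times Time vector in ms, one entry per sample, uniformly spaced.
#' @param channel_labels One label per channel.
#' @param condition Condition tag, e.g. `"ST"` or `"DT"`.
#' @param subject_id Subject identifier.
#' @param reject_mask Logical per-trial vector; `TRUE` marks a rejected
#'   trial. Defaults to all `FALSE`.
#' @return An object of class `EpochSet`.
#' @export
epoch_set <- function(data, times, channel_labels, condition = "ST",
                      subject_id = "S01", reject_mask = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[2] != length(channel_labels))
    stop("channel_labels length does not match channel dimension")
  if (dim(data)[3] != length(times))
    stop("times length does not match sample dimension")
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9)
    stop("times must be strictly increasing and uniformly spaced")
  if (is.null(reject_mask)) reject_mask <- rep(FALSE, dim(data)[1])
  if (length(reject_mask) != dim(data)[1])
    stop("reject_mask length does not match trial count")
  structure(list(data = data, times = times,
                 channel_labels = channel_labels, condition = condition,
                 subject_id = subject_id,
                 reject_mask = as.logical(reject_mask)),
            class = "EpochSet")
}

#' @export
print.EpochSet <- function(x, ...) {
  d <- dim(x$data)
  cat("<EpochSet> subject ", x$subject_id, " [", x$condition, "]: ",
      d[1], " trials x ", d[2], " channels x ", d[3], " samples, ",
      sum(x$reject_mask), " rejected, t = [", x$times[1], ", ",
      x$times[length(x$times)], "] ms\n", sep = "")
  invisible(x)
}

n_trials <- function(e) dim(e$data)[1]

sampling_rate_of <- function(e) 1000 / (e$times[2] - e$times[1])

channel_index <- function(e, label) {
  i <- match(label, e$channel_labels)
  if (is.na(i)) stop("channel '", label, "' not found")
  i
}

# Trials surviving the rejection mask, as a trials x channels x samples array.
usable_data <- function(e) {
  keep <- !e$reject_mask
  if (!any(keep)) stop("no usable (non-rejected) trials")
  e$data[keep, , , drop = FALSE]
}

#' Concatenate epoch sets along the trial dimension
#'
#' Channel labels and time axes must match; rejection masks are carried
#' through. Useful for fitting session-wide estimates (e.g. ocular
#' correction) across conditions.
#'
#' @param ... Two or more [epoch_set()] objects.
#' @param condition Condition tag of the result (default `"pooled"`).
#' @return An [epoch_set()].
#' @export
bind_epochs <- function(..., condition = "pooled") {
  sets <- list(...)
  stopifnot(length(sets) >= 2)
  ref <- sets[[1]]
  for (e in sets[-1]) {
    stopifnot(inherits(e, "EpochSet"))
    if (!identical(e$channel_labels, ref$channel_labels) ||
        !isTRUE(all.equal(e$times, ref$times)))
      stop("epoch sets differ in channels or time axis")
  }
  ntr <- vapply(sets, n_trials, integer(1))
  arr <- array(0, c(sum(ntr), length(ref$channel_labels),
                    length(ref$times)))
  at <- 0L
  for (e in sets) {
    arr[at + seq_len(n_trials(e)), , ] <- e$data
    at <- at + n_trials(e)
  }
  epoch_set(arr, ref$times, ref$channel_labels, condition = condition,
            subject_id = ref$subject_id,
            reject_mask = unlist(lapply(sets, `[[`, "reject_mask")))
}

#' Segment a continuous recording into epochs
#'
#' Cuts a half-open window `[window_ms[1], window_ms[2])` around every marker
#' matching `marker_label`. Events whose window would reach beyond either end
#' of the recording are dropped (with a message). With the defaults of the
#' study design (-200..1000 ms at 500 Hz) each trial has 600 samples and
#' stimulus onset is sample 101.
#'
#' @param rec A [continuous_recording()].
#' @param marker_label Marker label to epoch around (e.g. `"S1"`).
#' @param window_ms Length-2 window in ms relative to the marker, start < end.
#' @param condition,subject_id Tags stored on the result.
#' @return An [epoch_set()], trials ordered by marker onset.
#' @export
epoch <- function(rec, marker_label, window_ms = c(-200, 1000),
                  condition = "ST", subject_id = "S01") {
  stopifnot(inherits(rec, "ContinuousRecording"))
  onsets <- rec$markers$sample[rec$markers$label == marker_label]
  if (!length(onsets)) stop("no markers with label '", marker_label, "'")
  onsets <- sort(onsets)
  fs <- rec$sampling_rate
  k0 <- round(window_ms[1] * fs / 1000)
  k1 <- round(window_ms[2] * fs / 1000) - 1L  # half-open end
  nsamp <- k1 - k0 + 1L
  ok <- (onsets + k0 >= 1) & (onsets + k1 <= ncol(rec$data))
  if (any(!ok))
    message(sum(!ok), " event(s) too close to the recording edge dropped")
  onsets <- onsets[ok]
  if (!length(onsets)) stop("all matching events fall outside the recording")
  arr <- array(0, dim = c(length(onsets), nrow(rec$data), nsamp))
  for (i in seq_along(onsets))
    arr[i, , ] <- rec$data[, (onsets[i] + k0):(onsets[i] + k1)]
  times <- (k0:k1) * 1000 / fs
  epoch_set(arr, times, rec$channel_labels, condition = condition,
            subject_id = subject_id)
}
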