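# Preprocessing: common average reference, HEOG-based trial rejection and
# regression-based blink correction.

#' Common average reference
#'
#' Re-references every included channel to the instantaneous mean over the
#' included channels; excluded channels (by default the ocular ones) are left
#' untouched. Idempotent.
#'
#' @param x An [epoch_set()] or [continuous_recording()].
#' @param exclude_labels Channels excluded from (and untouched by) the
#'   reference; default the EOG channels.
#' @return Same class as `x`.
#' @export
common_average_reference <- function(x, exclude_labels = eog_channels()) {
  UseMethod("common_average_reference")
}

#' @export
common_average_reference.ContinuousRecording <- function(
    x, exclude_labels = eog_channels()) {
  incl <- !(x$channel_labels %in% exclude_labels)
  if (sum(incl) < 2) stop("need >= 2 included channels for a common average")
  ref <- colMeans(x$data[incl, , drop = FALSE])
  x$data[incl, ] <- sweep(x$data[incl, , drop = FALSE], 2, ref)
  x
}

#' @export
common_average_reference.EpochSet <- function(
    x, exclude_labels = eog_channels()) {
  incl <- !(x$channel_labels %in% exclude_labels)
  if (sum(incl) < 2) stop("need >= 2 included channels for a common average")
  ref <- apply(x$data[, incl, , drop = FALSE], c(1, 3), mean)
  x$data[, incl, ] <- x$data[, incl, , drop = FALSE] -
    aperm(array(ref, c(dim(ref), sum(incl))), c(1, 3, 2))
  x
}

#' Reject trials with horizontal eye movements
#'
#' Flags (does not delete) every trial whose absolute HEOG exceeds the
#' threshold at any sample. "Exceeding +/-50 uV" is read strictly: a peak of
#' exactly 50 uV is kept. Rejection is monotone in the threshold.
#'
#' @param e An [epoch_set()].
#' @param heog_channel HEOG channel label (default `"HEOG"`).
#' @param threshold_uv Rejection threshold in microvolts (default 50).
#' @return The epoch set with an updated `reject_mask` (previous rejections
#'   are kept) and attribute `n_rejected_heog`.
#' @export
reject_heog <- function(e, heog_channel = "HEOG", threshold_uv = 50) {
  stopifnot(inherits(e, "EpochSet"))
  i <- channel_index(e, heog_channel)
  peak <- apply(abs(e$data[, i, , drop = FALSE]), 1, max)
  bad <- peak > threshold_uv
  message(sum(bad), " of ", n_trials(e),
          " trials exceed +/-", threshold_uv, " uV on ", heog_channel)
  e$reject_mask <- e$reject_mask | bad
  attr(e, "n_rejected_heog") <- sum(bad)
  e
}

#' Regression-based blink correction
#'
#' Estimates, per scalp channel, the VEOG propagation factor b by least
#' squares pooled over all usable trials and samples, and subtracts
#' `b * VEOG` from the channel. With `subtract_average = TRUE` (default) the
#' factors are estimated on average-subtracted residuals — blinks occur at
#' trial-random times and survive the subtraction, while event-related
#' activity (which would otherwise leak into b through chance covariance
#' with blink timing) is removed; the correction itself is applied to the
#' unmodified data. On the estimation data, least-squares orthogonality
#' makes the pooled VEOG-scalp covariance zero after correction, and the
#' VEOG-explained variance of every channel can only decrease.
#'
#' @param e An [epoch_set()].
#' @param veog_channel VEOG channel label (default `"VEOG"`).
#' @param exclude_labels Channels not corrected (default the EOG pair).
#' @param subtract_average Estimate on trial-average-subtracted residuals
#'   (default `TRUE`).
#' @return List with `epochs` (corrected data), `propagation` (named
#'   per-channel factors, `NA` for uncorrected channels) and `skipped`
#'   (`TRUE` when VEOG had ~zero variance and the data were left unchanged).
#' @export
correct_blinks <- function(e, veog_channel = "VEOG",
                           exclude_labels = eog_channels(),
                           subtract_average = TRUE) {
  stopifnot(inherits(e, "EpochSet"))
  keep <- !e$reject_mask
  if (sum(keep) < 2) stop("blink correction needs >= 2 usable trials")
  iv <- channel_index(e, veog_channel)
  est <- e$data[keep, , , drop = FALSE]
  if (subtract_average) {
    avg <- apply(est, c(2, 3), mean)
    for (i in seq_len(dim(est)[1]))
      est[i, , ] <- est[i, , ] - avg
  }
  v <- as.vector(est[, iv, ])
  v <- v - mean(v)
  prop <- rep(NA_real_, length(e$channel_labels))
  names(prop) <- e$channel_labels
  if (stats::var(v) < 1e-12) {
    warning("VEOG variance ~ 0; blink correction skipped")
    return(list(epochs = e, propagation = prop, skipped = TRUE))
  }
  vv <- sum(v * v)
  scalp <- which(!(e$channel_labels %in% exclude_labels))
  for (ci in scalp) {
    y <- as.vector(est[, ci, ])
    b <- sum(v * (y - mean(y))) / vv
    prop[ci] <- b
    e$data[, ci, ] <- e$data[, ci, , drop = FALSE] -
      b * e$data[, iv, , drop = FALSE]
  }
  list(epochs = e, propagation = prop, skipped = FALSE)
}
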