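# Temporal Spectral Evolution: band-pass, rectify, average, baseline-correct.
#
# Three amplitude time courses per channel:
#   evoked  = rectified band-passed trial average (phase-locked activity),
#   total   = trial average of rectified band-passed single trials,
#   induced = total - evoked (the non-phase-locked remainder).
# Both evoked and total are baseline-corrected over the same window before
# the subtraction, so the identity induced + evoked = total holds at machine
# precision by construction. Before baseline correction evoked <= total
# pointwise (|mean| <= mean|.|, Jensen).

baseline_correct <- function(mat, times, baseline_ms) {
  if (is.null(baseline_ms)) return(mat)
  idx <- window_samples(times, baseline_ms)
  mat - rowMeans(mat[, idx, drop = FALSE])
}

#' ERP: time-domain trial average
#'
#' Mean over non-rejected trials, baseline-corrected over the full
#' pre-stimulus interval by default.
#'
#' @param e An [epoch_set()].
#' @param baseline_ms ERP baseline window in ms (default `c(-200, 0)`);
#'   `NULL` for none.
#' @return channels x samples matrix (rownames = channel labels).
#' @export
erp_average <- function(e, baseline_ms = c(-200, 0)) {
  stopifnot(inherits(e, "EpochSet"))
  erp <- apply(usable_data(e), c(2, 3), mean)
  rownames(erp) <- e$channel_labels
  baseline_correct(erp, e$times, baseline_ms)
}

#' Spectrally evoked activity
#'
#' Rectified alpha-band-filtered ERP, baseline-corrected: the amplitude time
#' course of the phase-locked component.
#'
#' @param erp channels x samples ERP matrix (from [erp_average()]).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @param baseline_ms Spectral baseline window (default `c(-100, 0)`);
#'   `NULL` skips baseline correction.
#' @param times Time vector in ms matching the columns of `erp`.
#' @return channels x samples matrix.
#' @export
evoked_spectral <- function(erp, fs, spec = filter_spec(),
                            baseline_ms = c(-100, 0),
                            times = NULL) {
  if (is.null(times))
    stop("times must be supplied to place the baseline window")
  r <- abs(bandpass_zero_phase(erp, fs, spec, .audit_tag = "evoked"))
  baseline_correct(r, times, baseline_ms)
}

#' Total TSE activity
#'
#' Each usable trial is band-pass filtered and rectified; the rectified
#' amplitudes are averaged across trials and baseline-corrected.
#'
#' @inheritParams evoked_spectral
#' @param e An [epoch_set()].
#' @return channels x samples matrix.
#' @export
tse_total <- function(e, fs = sampling_rate_of(e), spec = filter_spec(),
                      baseline_ms = c(-100, 0)) {
  stopifnot(inherits(e, "EpochSet"))
  x <- usable_data(e)
  r <- abs(bandpass_zero_phase(x, fs, spec, .audit_tag = "total"))
  tot <- apply(r, c(2, 3), mean)
  rownames(tot) <- e$channel_labels
  baseline_correct(tot, e$times, baseline_ms)
}

#' Evoked / total / induced TSE decomposition
#'
#' Runs both TSE branches (each applies the band-pass exactly once) and
#' subtracts the baseline-corrected evoked trace from the baseline-corrected
#' total to isolate the induced, non-phase-locked component.
#'
#' @param e An [epoch_set()].
#' @param fs Sampling rate (Hz); defaults to the epoch set's.
#' @param spec A [filter_spec()].
#' @param baseline_ms Spectral baseline (default `c(-100, 0)`); `NULL` for
#'   uncorrected traces.
#' @param erp_baseline_ms Pre-stimulus DC baseline subtracted from every
#'   trial before filtering (default `c(-200, 0)`; `NULL` for none).
#'   Applying it per trial (rather than to the ERP only) keeps the two
#'   branches algebraically identical on identical trials.
#' @return Object of class `TseTraces`: list with `evoked`, `total`,
#'   `induced` (channels x samples), `times`, `channel_labels`,
#'   `baseline_window`, `n_trials_used`.
#' @export
tse_decompose <- function(e, fs = sampling_rate_of(e), spec = filter_spec(),
                          baseline_ms = c(-100, 0),
                          erp_baseline_ms = c(-200, 0)) {
  stopifnot(inherits(e, "EpochSet"))
  if (!is.null(erp_baseline_ms)) {
    idx <- window_samples(e$times, erp_baseline_ms)
    bl <- apply(e$data[, , idx, drop = FALSE], c(1, 2), mean)
    e$data <- e$data - array(bl, dim = dim(e$data))
  }
  erp <- erp_average(e, baseline_ms = NULL)
  ev <- evoked_spectral(erp, fs, spec, baseline_ms, times = e$times)
  tot <- tse_total(e, fs, spec, baseline_ms)
  structure(list(evoked = ev, total = tot, induced = tot - ev,
                 times = e$times, channel_labels = e$channel_labels,
                 baseline_window = baseline_ms,
                 n_trials_used = sum(!e$reject_mask)),
            class = "TseTraces")
}

#' @export
print.TseTraces <- function(x, ...) {
  cat("<TseTraces> ", nrow(x$total), " channels x ", ncol(x$total),
      " samples, ", x$n_trials_used, " trials",
      if (!is.null(x$baseline_window))
        paste0(", baseline [", x$baseline_window[1], ", ",
               x$baseline_window[2], "] ms"),
      "\n", sep = "")
  invisible(x)
}

#' Export TSE traces as tab-separated text
#'
#' One file per component: channels x time, first row the time axis in ms.
#'
#' @param traces A `TseTraces` object.
#' @param path Base path; `_evoked.tsv`, `_total.tsv`, `_induced.tsv` are
#'   appended.
#' @return Invisibly, the written paths.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "TseTraces"))
  out <- character(0)
  for (comp in c("evoked", "total", "induced")) {
    f <- paste0(path, "_", comp, ".tsv")
    m <- traces[[comp]]
    df <- data.frame(channel = traces$channel_labels, m,
                     check.names = FALSE)
    names(df) <- c("channel", format(traces$times, trim = TRUE))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, f)
  }
  invisible(out)
}
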