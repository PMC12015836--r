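# Peak-latency and mean-amplitude measurement in named windows at named
# electrodes, plus the 6 x 7 electrode-matrix amplitude table feeding the
# ANOVA layer.
#
# Default analysis windows (closed, ms): P3 350-410; evoked alpha 140-155;
# induced alpha 165-200. Latencies are reported on the sample grid (2 ms at
# 500 Hz) without interpolation; ties break to the earliest sample.

#' Default measurement windows (ms)
#' @return Named list: `p3`, `evoked_alpha`, `induced_alpha`.
#' @export
measurement_windows <- function() {
  list(p3 = c(350, 410), evoked_alpha = c(140, 155),
       induced_alpha = c(165, 200))
}

#' Peak latency and amplitude in a window
#'
#' Finds the extremum of `trace` within the closed window. `polarity "max"`
#' takes the maximum, `"min"` the minimum, `"abs"` the sample of largest
#' absolute deviation (sign kept). A flat trace yields the earliest sample
#' and `degenerate = TRUE`.
#'
#' @param trace Numeric vector, one value per sample.
#' @param times Time vector in ms.
#' @param window_ms Closed search window.
#' @param polarity `"max"`, `"min"` or `"abs"`.
#' @return List: `latency_ms`, `amplitude_uv`, `polarity`,
#'   `search_window_ms`, `degenerate`.
#' @export
peak_latency <- function(trace, times, window_ms, polarity = "max") {
  idx <- window_samples(times, window_ms)
  seg <- trace[idx]
  k <- switch(polarity,
              max = which.max(seg),
              min = which.min(seg),
              abs = which.max(abs(seg)),
              stop("polarity must be 'max', 'min' or 'abs'"))
  list(latency_ms = times[idx[k]], amplitude_uv = seg[k],
       polarity = polarity, search_window_ms = window_ms,
       degenerate = diff(range(seg)) == 0)
}

#' Mean amplitude in a window
#'
#' Arithmetic mean of the samples inside the closed window.
#'
#' @inheritParams peak_latency
#' @return Mean amplitude in microvolts.
#' @export
mean_amplitude <- function(trace, times, window_ms) {
  mean(trace[window_samples(times, window_ms)])
}

#' Grand average across subjects
#'
#' @param traces List of equally shaped matrices or vectors (one per
#'   subject).
#' @return Pointwise mean, same shape as each element.
#' @export
grand_average <- function(traces) {
  stopifnot(length(traces) >= 1)
  d1 <- dim(traces[[1]]) %||% length(traces[[1]])
  for (tr in traces)
    if (!identical(dim(tr) %||% length(tr), d1))
      stop("all subject traces must have identical shape")
  Reduce(`+`, traces) / length(traces)
}

#' Pick the measurement electrode from a grand average
#'
#' Returns the channel whose window extremum has the largest magnitude in
#' the grand-average trace; per-subject measurements are then all taken at
#' that electrode.
#'
#' @param grand channels x samples matrix with channel-label rownames.
#' @param times Time vector in ms.
#' @param window_ms Closed search window.
#' @param polarity Passed to [peak_latency()].
#' @param exclude Labels never eligible (default the ocular channels).
#' @return Channel label.
#' @export
pick_measurement_electrode <- function(grand, times, window_ms,
                                       polarity = "max",
                                       exclude = eog_channels()) {
  stopifnot(!is.null(rownames(grand)))
  grand <- grand[!(rownames(grand) %in% exclude), , drop = FALSE]
  mags <- vapply(seq_len(nrow(grand)), function(i)
    abs(peak_latency(grand[i, ], times, window_ms, polarity)$amplitude_uv),
    numeric(1))
  rownames(grand)[which.max(mags)]
}

#' Electrode-matrix mean amplitudes
#'
#' Mean amplitude in the window for every cell of the 6 x 7 electrode
#' matrix, in long format keyed for the repeated-measures ANOVA.
#'
#' @param trace channels x samples matrix with label rownames (one subject,
#'   one condition).
#' @param times Time vector (ms).
#' @param window_ms Closed measurement window.
#' @param subject,condition Tags for the output rows.
#' @param matrix_labels Electrode grid, default [electrode_matrix()].
#' @return Data frame: subject, condition, ap (anterior-posterior level),
#'   lm (lateral-medial line), electrode, amplitude_uv. 42 rows.
#' @export
matrix_amplitudes <- function(trace, times, window_ms, subject = "S01",
                              condition = "ST",
                              matrix_labels = electrode_matrix()) {
  missing <- setdiff(as.vector(matrix_labels), rownames(trace))
  if (length(missing))
    stop("matrix electrodes not present in trace: ",
         paste(missing, collapse = ", "))
  grid <- expand.grid(ap = rownames(matrix_labels),
                      lm = colnames(matrix_labels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$electrode <- matrix_labels[cbind(grid$ap, grid$lm)]
  grid$amplitude_uv <- vapply(grid$electrode, function(ch)
    mean_amplitude(trace[ch, ], times, window_ms), numeric(1))
  data.frame(subject = subject, condition = condition, grid,
             row.names = NULL)
}
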