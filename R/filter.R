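# Zero-phase Butterworth band-pass filtering.
#
# The alpha-band filter is specified as "48 dB/octave", read as the one-pass
# asymptotic rolloff of 6 dB/octave per pole, i.e. an order-8 band-pass
# design. Forward-backward (filtfilt) application cancels the phase response
# and doubles the magnitude attenuation; that doubling is accepted as part of
# "zero phase". The design goes through the pole-zero route (analog
# Butterworth prototype -> band-pass s-plane transform -> bilinear transform,
# via the signal package's Zpg tools) and is executed as a cascade of
# second-order sections: an order-16 transfer-function polynomial with a
# passband at 0.03-0.05 of Nyquist is numerically fragile, the biquad
# cascade is not.

#' Band-pass filter specification
#'
#' @param band Length-2 passband edges in Hz (default the alpha band, 8-13).
#' @param rolloff_db_oct Asymptotic one-pass rolloff in dB/octave; must be a
#'   multiple of 6. Default 48 (an order-8 Butterworth).
#' @return Object of class `FilterSpec`.
#' @export
filter_spec <- function(band = c(8, 13), rolloff_db_oct = 48) {
  stopifnot(length(band) == 2)
  if (!(band[1] > 0 && band[1] < band[2]))
    stop("band must satisfy 0 < low < high")
  order <- rolloff_db_oct / 6
  if (order != round(order) || order < 1)
    stop("rolloff_db_oct must be a positive multiple of 6")
  structure(list(band = as.numeric(band), family = "butterworth",
                 rolloff_db_oct = rolloff_db_oct, order = as.integer(order),
                 zero_phase = TRUE),
            class = "FilterSpec")
}

# Second-order-section design. Returns list(sos = n x 6 matrix
# [b0 b1 b2 1 a1 a2], zpg = the designed pole-zero-gain form).
butter_bandpass_sos <- function(fs, spec) {
  lo <- spec$band[1]; hi <- spec$band[2]; n <- spec$order
  if (hi >= fs / 2) stop("band upper edge (", hi,
                         " Hz) must be below Nyquist (", fs / 2, " Hz)")
  W <- c(lo, hi) / (fs / 2)
  k <- seq_len(n)
  proto <- signal::Zpg(zero = numeric(0),
                       pole = exp(1i * pi * (2 * k + n - 1) / (2 * n)),
                       gain = 1)
  Tbil <- 2
  Wwarp <- (2 / Tbil) * tan(pi * W / 2)        # prewarped edges
  bp <- signal::sftrans(proto, W = Wwarp, stop = FALSE)
  dz <- signal::bilinear(bp, T = Tbil)

  # Pair conjugate poles into biquads; each section takes one zero at z = +1
  # and one at z = -1 (the band-pass zeros), with the overall gain spread
  # evenly so intermediate section outputs stay well scaled.
  p <- dz$pole
  pu <- p[Im(p) > 0]
  pu <- pu[order(abs(pu))]
  gsec <- abs(dz$gain)^(1 / length(pu))
  sos <- t(vapply(pu, function(pk) {
    c(gsec * c(1, 0, -1), 1, -2 * Re(pk), abs(pk)^2)
  }, numeric(6)))
  list(sos = sos, zpg = dz, fs = fs)
}

# One forward pass of the biquad cascade over the columns of matrix x
# (time x signals), direct-form II transposed, vectorized across signals.
sos_filter_matrix <- function(sos, x) {
  nsig <- ncol(x)
  for (s in seq_len(nrow(sos))) {
    b0 <- sos[s, 1]; b1 <- sos[s, 2]; b2 <- sos[s, 3]
    a1 <- sos[s, 5]; a2 <- sos[s, 6]
    z1 <- numeric(nsig); z2 <- numeric(nsig)
    for (t in seq_len(nrow(x))) {
      xt <- x[t, ]
      yt <- b0 * xt + z1
      z1 <- b1 * xt - a1 * yt + z2
      z2 <- b2 * xt - a2 * yt
      x[t, ] <- yt
    }
  }
  x
}

# Internal audit of filter applications: pipeline code tags each band-pass
# call with the branch it serves so tests can assert that every analysis
# branch filters exactly once.
.filter_audit <- new.env(parent = emptyenv())
filter_audit_reset <- function() assign("log", character(0), .filter_audit)
filter_audit_log <- function() get0("log", .filter_audit, ifnotfound = character(0))
filter_audit_record <- function(tag) {
  if (!is.null(tag))
    assign("log", c(filter_audit_log(), tag), .filter_audit)
}

#' Zero-phase band-pass filtering
#'
#' Applies the Butterworth band-pass of `spec` forward and backward along
#' time, giving zero net phase shift (a symmetric pulse keeps its peak
#' sample). Signals are extended by odd reflection over one filter-settling
#' length on each side before filtering, and the padding is discarded.
#'
#' @param x Numeric vector (samples), matrix (signals x samples) or 3-d array
#'   (trials x channels x samples); filtering runs along the last dimension.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @param .audit_tag Internal branch tag for the filter-call audit.
#' @return Same shape as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, spec = filter_spec(),
                                .audit_tag = NULL) {
  filter_audit_record(.audit_tag)
  des <- butter_bandpass_sos(fs, spec)
  dims <- dim(x)
  if (is.null(dims)) {
    m <- matrix(x, ncol = 1)
  } else if (length(dims) == 2) {
    m <- t(x)
  } else if (length(dims) == 3) {
    m <- matrix(aperm(x, c(3, 1, 2)), nrow = dims[3])
  } else stop("x must have at most 3 dimensions")

  nsamp <- nrow(m)
  minlen <- 3 * (2 * spec$order + 1)
  if (nsamp <= minlen)
    stop("signal too short to filter (", nsamp, " samples, need > ",
         minlen, ")")
  pad <- min(nsamp - 1L, ceiling(3 * fs / spec$band[1]))
  first <- m[1, , drop = FALSE]; last <- m[nsamp, , drop = FALSE]
  ext <- rbind(
    first[rep(1, pad), , drop = FALSE] * 2 - m[(pad + 1):2, , drop = FALSE],
    m,
    last[rep(1, pad), , drop = FALSE] * 2 -
      m[(nsamp - 1):(nsamp - pad), , drop = FALSE])
  ext <- sos_filter_matrix(des$sos, ext)
  ext <- sos_filter_matrix(des$sos, ext[nrow(ext):1, , drop = FALSE])
  ext <- ext[nrow(ext):1, , drop = FALSE]
  out <- ext[(pad + 1):(pad + nsamp), , drop = FALSE]

  if (is.null(dims)) drop(out)
  else if (length(dims) == 2) t(out)
  else aperm(array(out, dim = c(dims[3], dims[1], dims[2])), c(2, 3, 1))
}

#' Filter magnitude response
#'
#' One-pass magnitude response of the designed digital filter at frequencies
#' `f`, plus the analytic magnitude of the underlying analog Butterworth
#' band-pass evaluated at the bilinear-prewarped frequencies (the design
#' target the digital filter realizes exactly).
#'
#' @param fs Sampling rate (Hz); `f` frequencies to evaluate (Hz);
#'   `spec` a [filter_spec()].
#' @return Data frame with columns `f`, `mag` (designed digital filter) and
#'   `mag_analytic` (analog prototype at prewarped frequencies).
#' @export
filter_response <- function(fs, f, spec = filter_spec()) {
  des <- butter_bandpass_sos(fs, spec)
  z <- exp(1i * 2 * pi * f / fs)
  H <- rep(complex(real = 1), length(f))
  for (s in seq_len(nrow(des$sos))) {
    num <- des$sos[s, 1] + des$sos[s, 2] / z + des$sos[s, 3] / z^2
    den <- 1 + des$sos[s, 5] / z + des$sos[s, 6] / z^2
    H <- H * num / den
  }
  # analog band-pass |H|: lowpass prototype order n at the warped frequency
  lo <- spec$band[1] / (fs / 2); hi <- spec$band[2] / (fs / 2)
  wl <- tan(pi * lo / 2); wh <- tan(pi * hi / 2)
  w <- tan(pi * f / fs)
  Wn <- (w^2 - wl * wh) / (w * (wh - wl))
  mag_an <- 1 / sqrt(1 + Wn^(2 * spec$order))
  data.frame(f = f, mag = abs(H), mag_analytic = mag_an)
}
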