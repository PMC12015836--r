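#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation. All randomness in the package flows from
# one master seed; independent streams (per subject, condition, component) get
# their own seed via a small string hash so modules can be exercised in
# isolation and still reproduce bit-identically inside the full pipeline.
# Arithmetic stays below 2^53 so the modulo is exact in doubles; results are
# valid 32-bit R integers.
split_seed <- function(seed, ...) {
  keys <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 2166136261
  for (code in utf8ToInt(keys)) {
    h <- ((h * 131) %% 2147483629 + code) %% 2147483629
  }
  as.integer(h %% 2147483562L + 1L)
}

# Run an expression with a private RNG state so library/simulation calls do
# not disturb (or depend on) the caller's .Random.seed.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Closed-window sample selection: printed analysis windows (e.g. 350-410 ms)
# are closed on both ends with nearest-sample rounding, so results are
# bit-stable across platforms.
window_samples <- function(times, window_ms) {
  stopifnot(length(window_ms) == 2, window_ms[1] <= window_ms[2])
  dt <- times[2] - times[1]
  i0 <- which.min(abs(times - window_ms[1]))
  i1 <- which.min(abs(times - window_ms[2]))
  if (times[i0] < window_ms[1] - dt / 2) i0 <- i0 + 1L
  if (times[i1] > window_ms[2] + dt / 2) i1 <- i1 - 1L
  if (i1 < i0) stop("window [", window_ms[1], ", ", window_ms[2],
                    "] ms contains no samples")
  i0:i1
}

# round() in R rounds half to even; grand-average latencies are reported with
# conventional half-up rounding (148.5 -> 149).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
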