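# TSE decomposition: construction identity, analytic amplitude, dissociation.

test_that("induced + evoked = total at machine precision", {
  p <- small_params(n_trials = 20, seed = 31)
  e <- simulate_subject(p, 1, "ST")$epochs
  tt <- tse_decompose(e)
  expect_lt(max(abs(tt$induced + tt$evoked - tt$total)), 1e-12)
  expect_identical(tt$n_trials_used, 20L)
})

test_that("evoked <= total pointwise before baseline correction", {
  for (seed in c(37, 38)) {
    p <- small_params(n_trials = 15, seed = seed)
    e <- simulate_subject(p, 1, "DT")$epochs
    erp <- erp_average(e, baseline_ms = NULL)
    ev <- evoked_spectral(erp, 500, baseline_ms = NULL, times = e$times)
    tot <- tse_total(e, baseline_ms = NULL)
    expect_true(all(ev <= tot + 1e-10))
  }
})

test_that("a single trial makes total equal the rectified filtered trial", {
  p <- small_params(n_trials = 1, seed = 41)
  e <- simulate_subject(p, 1, "ST")$epochs
  erp <- erp_average(e, baseline_ms = NULL)
  expect_equal(tse_total(e, baseline_ms = NULL),
               evoked_spectral(erp, 500, baseline_ms = NULL,
                               times = e$times))
})

test_that("identical trials give zero induced activity", {
  p <- params_with_only(c("p3", "evoked_alpha"), seed = 43, n_trials = 25)
  e <- simulate_subject(p, 1, "ST")$epochs
  # all per-trial randomness is off: trials are identical
  expect_lt(max(abs(sweep(e$data, c(2, 3), e$data[1, , ]))), 1e-12)
  tt <- tse_decompose(e)
  expect_lt(max(abs(tt$induced)), 1e-9)
})

test_that("traces have zero mean in the baseline window after correction", {
  p <- small_params(n_trials = 10, seed = 47)
  tt <- tse_decompose(simulate_subject(p, 2, "DT")$epochs)
  idx <- tt$times >= -100 & tt$times <= 0
  for (comp in c("evoked", "total", "induced"))
    expect_lt(max(abs(rowMeans(tt[[comp]][, idx]))), 1e-9)
})

test_that("doubling the ERP doubles the evoked trace before baseline", {
  p <- small_params(n_trials = 8, seed = 53)
  e <- simulate_subject(p, 1, "ST")$epochs
  erp <- erp_average(e)
  a <- evoked_spectral(erp, 500, baseline_ms = NULL, times = e$times)
  b <- evoked_spectral(2 * erp, 500, baseline_ms = NULL, times = e$times)
  expect_equal(b, 2 * a)
})

test_that("ongoing alpha of amplitude A gives a flat 2A/pi total", {
  A <- 2
  p <- params_with_only("induced_alpha", seed = 59, n_trials = 140,
                        induced_alpha = list(depth = 0),
                        channels = c("PO6", "VEOG", "HEOG"))
  e <- simulate_subject(p, 1, "ST")$epochs
  tot <- tse_total(e, baseline_ms = NULL)
  probe <- which(e$times == 400)
  se <- A * sqrt(1 / 2 - 4 / pi^2) / sqrt(140)   # sd of |A sin| / sqrt(n)
  expect_lt(abs(tot["PO6", probe] - 2 * A / pi), 3 * se)
})

test_that("trace matches a dense phase-quadrature oracle of the envelope", {
  # oracle: average |filtered envelope-modulated sinusoid| over a dense
  # deterministic phase grid, instead of random trial phases
  p <- params_with_only("induced_alpha", seed = 61, n_trials = 140,
                        induced_alpha = list(latency_sd = 0),
                        channels = c("PO6", "VEOG", "HEOG"))
  r <- simulate_subject(p, 1, "ST")
  tt <- tse_decompose(r$epochs, baseline_ms = NULL)
  times <- tt$times; tsec <- times / 1000
  ia <- p$induced_alpha
  env <- 1 - ia$depth * exp(-(times - r$truth$induced_trough_ms)^2 /
                              (2 * (ia$width_ms / 2.355)^2))
  phis <- (seq_len(64) - 0.5) / 64 * 2 * pi
  osc <- vapply(phis, function(ph)
    ia$amplitude * env * sin(2 * pi * ia$frequency * tsec + ph),
    numeric(length(times)))
  oracle <- colMeans(abs(bandpass_zero_phase(t(osc), 500)))
  mid <- times >= -100 & times <= 900
  se <- ia$amplitude * sqrt(1 / 2 - 4 / pi^2) / sqrt(140)
  expect_lt(max(abs(tt$total["PO6", mid] - oracle[mid])), 4 * se)
})

test_that("dense evenly spaced phases localize the trough exactly and at
           (2/pi) x depth", {
  # deterministic limit of the random-phase average: build the epochs
  # directly with phases 2*pi*k/n, so the total trace is the quadrature
  # mean and the trough argmin must sit on the envelope argmin
  fs <- 500; times <- seq(-200, by = 2, length.out = 600)
  tsec <- times / 1000
  A <- 2; d <- 0.5; L <- 184; sig <- 200 / 2.355
  env <- 1 - d * exp(-(times - L)^2 / (2 * sig^2))
  n <- 64
  arr <- array(0, c(n, 1, 600))
  for (k in seq_len(n))
    arr[k, 1, ] <- A * env * sin(2 * pi * 10 * tsec + 2 * pi * k / n)
  e <- epoch_set(arr, times, "PO6")
  tt <- tse_decompose(e, baseline_ms = NULL)
  trough <- peak_latency(tt$induced["PO6", ], times, c(60, 340), "min")
  expect_equal(trough$latency_ms, L, tolerance = 4)
  # trough depth: (2/pi) * d * A, diluted by the band-pass response to the
  # 200 ms FWHM envelope notch (which keeps most of it)
  level <- mean(tt$induced["PO6", times >= 600 & times <= 900])
  depth <- level - trough$amplitude_uv
  expect_gt(depth, 0.6 * (2 / pi) * d * A)
  expect_lt(depth, 1.05 * (2 / pi) * d * A)
})

test_that("random-phase alpha leaves only a small evoked residue", {
  p <- params_with_only("induced_alpha", seed = 67, n_trials = 140,
                        channels = c("PO6", "VEOG", "HEOG"))
  tt <- tse_decompose(simulate_subject(p, 1, "ST")$epochs)
  # residual phase-locked content shrinks ~1/sqrt(140); the trough does not
  expect_lt(sqrt(mean(tt$evoked["PO6", ]^2)),
            0.5 * abs(min(tt$induced["PO6", ])))
})

test_that("each decomposition branch applies the band-pass exactly once", {
  p <- small_params(n_trials = 5, seed = 71)
  e <- simulate_subject(p, 1, "ST")$epochs
  alphatse:::filter_audit_reset()
  tse_decompose(e)
  log <- alphatse:::filter_audit_log()
  expect_identical(sum(log == "evoked"), 1L)
  expect_identical(sum(log == "total"), 1L)
})

test_that("trace export writes channels x time tables that read back", {
  p <- small_params(n_trials = 5, seed = 73)
  tt <- tse_decompose(simulate_subject(p, 1, "ST")$epochs)
  base <- file.path(withr::local_tempdir(), "tr")
  paths <- write_traces(tt, base)
  expect_length(paths, 3)
  got <- utils::read.delim(paths[3], check.names = FALSE)
  expect_identical(got$channel, tt$channel_labels)
  expect_equal(as.numeric(colnames(got)[-1]), tt$times)
  expect_equal(unname(as.matrix(got[, -1])), unname(tt$induced),
               tolerance = 1e-6)
})

test_that("latency estimators are exact on noise-free data", {
  for (seed in c(81, 82)) {
    # evoked burst alone: rectification ripple is symmetric about the
    # centre, so the trace argmax sits on the generating centre
    p <- params_with_only("evoked_alpha", seed = seed, n_trials = 20)
    r <- simulate_subject(p, 1, "ST")
    tt <- tse_decompose(r$epochs)
    burst <- peak_latency(tt$evoked["PO6", ], tt$times, c(100, 220), "max")
    expect_lt(abs(burst$latency_ms - r$truth$evoked_center_ms), 2.1)
  }
})

test_that("phase-locked and random-phase alpha interact nonlinearly in the
           subtraction (known limitation)", {
  # E|b + A e^{i phi}| < b + 2A/pi: where a phase-locked burst rides on
  # ongoing random-phase alpha, the induced trace acquires a spurious dip
  # at the burst latency even without noise
  p <- params_with_only(c("evoked_alpha", "induced_alpha"), seed = 85,
                        n_trials = 140,
                        evoked_alpha = list(burst_center = c(ST = 400,
                                                             DT = 400),
                                            center_sd = 0),
                        induced_alpha = list(depth = 0),
                        channels = c("PO6", "VEOG", "HEOG"))
  tt <- tse_decompose(simulate_subject(p, 1, "ST")$epochs)
  near <- tt$times >= 360 & tt$times <= 440
  far <- tt$times >= 600 & tt$times <= 900
  expect_lt(mean(tt$induced["PO6", near]),
            mean(tt$induced["PO6", far]) - 0.05)
})
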