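# Synthetic-data generator: validation, determinism, geometry, ground truth.

test_that("invalid parameters are rejected with the field named", {
  expect_error(simulation_params(induced_alpha = list(depth = 1.5)),
               "induced_alpha\\$depth")
  expect_error(simulation_params(evoked_alpha = list(frequency = 15)),
               "evoked_alpha\\$frequency")
  expect_error(simulation_params(epoch_window = c(100, 1000)),
               "epoch_window")
  expect_error(simulation_params(noise = list(rms = -1)), "noise")
  expect_error(simulation_params(p3 = list(banana = 1)), "banana")
  expect_error(simulation_params(n_subjects = 0), "n_subjects")
})

test_that("identical seed and params give bit-identical output", {
  p <- small_params(seed = 7)
  a <- simulate_subject(p, 1, "ST")
  b <- simulate_subject(p, 1, "ST")
  expect_identical(a$epochs$data, b$epochs$data)
  expect_identical(a$truth, b$truth)
  # and is insensitive to the caller's RNG state
  set.seed(123); runif(3)
  c_ <- simulate_subject(p, 1, "ST")
  expect_identical(a$epochs$data, c_$epochs$data)
})

test_that("different subjects, conditions and seeds decorrelate", {
  p <- small_params(seed = 7)
  a <- simulate_subject(p, 1, "ST")$epochs$data
  expect_false(identical(a, simulate_subject(p, 2, "ST")$epochs$data))
  expect_false(identical(a, simulate_subject(p, 1, "DT")$epochs$data))
  p2 <- small_params(seed = 8)
  expect_false(identical(a, simulate_subject(p2, 1, "ST")$epochs$data))
})

test_that("epoch geometry matches the study design", {
  p <- small_params(n_trials = 10)
  e <- simulate_subject(p, 1, "ST")$epochs
  expect_identical(dim(e$data), c(10L, 10L, 600L))
  expect_equal(e$times[1], -200)
  expect_equal(diff(e$times)[1], 2)
  expect_true(0 %in% e$times)
})

test_that("all-zero component amplitudes give identically zero epochs", {
  p <- do.call(simulation_params,
               c(list(n_subjects = 1, n_trials_per_condition = 5,
                      channels = small_channels(), seed = 3),
                 quiet_overrides()))
  e <- simulate_subject(p, 1, "ST")$epochs
  expect_identical(max(abs(e$data)), 0)
  tt <- tse_decompose(e, baseline_ms = NULL)
  expect_identical(max(abs(tt$total)), 0)
  expect_identical(max(abs(tt$induced)), 0)
})

test_that("ground-truth trough latency is the argmin of the envelope", {
  # noise-free: the only stochasticity left is the 140-draw phase sample,
  # whose 1/sqrt(n) rectified-average fluctuations still jitter the trace
  # argmin by up to ~20 ms (the deterministic dense-phase limit is tested
  # exactly in the TSE quadrature-oracle test)
  for (seed in 1:5) {
    p <- params_with_only("induced_alpha", seed = seed, n_trials = 140,
                          channels = c("PO6", "VEOG", "HEOG"))
    r <- simulate_subject(p, 1, "DT")
    tt <- tse_decompose(r$epochs, baseline_ms = NULL)
    trough <- peak_latency(tt$induced["PO6", ], tt$times, c(100, 340),
                           polarity = "min")
    expect_lt(abs(trough$latency_ms - r$truth$induced_trough_ms), 25)
    expect_true(r$truth$induced_trough_ms %in% tt$times)  # on the grid
  }
})

test_that("HEOG-flagged trials are exactly those exceeding the threshold", {
  p <- params_with_only("artifacts", seed = 11, n_trials = 60)
  r <- simulate_subject(p, 1, "ST")
  peak <- apply(abs(r$epochs$data[, 10, ]), 1, max)   # HEOG channel
  expect_identical(which(peak > 50), r$truth$heog_trials)
  expect_true(all(peak[r$truth$heog_trials] > 50))
})

test_that("with no evoked component the trial average cancels alpha", {
  # residual phase-locked alpha shrinks like 1/sqrt(n): at n = 140 the
  # evoked trace RMS stays below 3x the shrunk single-trial alpha RMS
  p <- params_with_only("induced_alpha", seed = 21, n_trials = 140,
                        induced_alpha = list(depth = 0))
  e <- simulate_subject(p, 1, "ST")$epochs
  tt <- tse_decompose(e, baseline_ms = NULL)
  single_rms <- p$induced_alpha$amplitude / sqrt(2)
  expect_lt(sqrt(mean(tt$evoked["PO6", ]^2)),
            3 * single_rms / sqrt(140))
})

test_that("generate_dataset bundles subjects, truth and behavior", {
  p <- small_params(n_trials = 6, seed = 2)
  ds <- generate_dataset(p)
  expect_named(ds$subjects, c("S01", "S02"))
  expect_named(ds$subjects$S01, c("ST", "DT"))
  expect_s3_class(ds$subjects$S02$DT, "EpochSet")
  expect_identical(nrow(ds$behavior), 4L)
  expect_true(all(ds$behavior$accuracy_pct <= 100))
  expect_length(ds$truth, 4)
})

test_that("behavioral RTs carry the condition effect with subject pairing", {
  p <- simulation_params(n_subjects = 40, channels = small_channels(),
                         seed = 5)
  b <- simulate_behavior(p)
  st <- b$rt_ms[b$condition == "ST"]; dt <- b$rt_ms[b$condition == "DT"]
  expect_gt(mean(dt) - mean(st), 20)    # true shift 63 ms
  expect_gt(cor(st, dt), 0.4)           # shared subject speed factor
})

test_that("fixtures roundtrip through the BrainVision writer", {
  p <- simulation_params(n_subjects = 1, n_trials_per_condition = 4,
                         channels = c("Pz", "PO6", "VEOG", "HEOG"),
                         seed = 13)
  ds <- generate_dataset(p)
  d <- withr::local_tempdir()
  sidecar <- write_fixture(ds, d)
  expect_true(file.exists(sidecar))
  rec <- read_brainvision(file.path(d, "S01_ST.vhdr"))
  e <- epoch(rec, "S1", c(-200, 1000), condition = "ST")
  expect_equal(e$data, ds$subjects$S01$ST$data, tolerance = 1e-5)
  meta <- jsonlite::read_json(sidecar)
  expect_identical(meta$n_subjects, 1L)
  expect_identical(meta$seed, 13L)
  expect_length(meta$truth, 2)
})
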