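# Ground-truth synthetic EEG generator.
#
# Emulates a two-condition (single-target ST vs double-target DT) go/no-go
# study: 26 subjects x 140 target trials per condition, 58 scalp channels
# plus VEOG/HEOG at 500 Hz, epochs -200..1000 ms around target onset. Each
# epoch is the sum of
#   (a) a P3-like midline-parietal slow positive wave (latency and amplitude
#       differ by condition),
#   (b) an early phase-locked alpha burst (identical phase on every trial),
#   (c) ongoing alpha with uniform-random per-trial phase whose envelope
#       carries a deterministic desynchronization trough (the induced,
#       non-phase-locked component),
#   (d) 1/f background noise, and
#   (e) ocular artifacts: VEOG blink pulses propagated to scalp channels by
#       fixed per-channel factors, and HEOG step deflections on a fraction
#       of trials.
# Every latent draw is recorded in a GroundTruth structure so downstream
# recovery can be scored. The ongoing alpha is a fixed-frequency sinusoid
# (not narrowband noise), which keeps the rectified-mean identity
# E|A sin| = 2A/pi exact for analytic checks.

#' Simulation parameters
#'
#' Builds (and validates) the full parameter set of the synthetic study.
#' Every argument can be partially overridden; unnamed sub-fields keep their
#' defaults. Condition-dependent fields are length-2 vectors named ST/DT.
#'
#' @param n_subjects Number of subjects (default 26).
#' @param n_trials_per_condition Target trials per condition (default 140).
#' @param sampling_rate Hz (default 500).
#' @param epoch_window Half-open epoch window in ms (default `c(-200, 1000)`).
#' @param channels Channel labels; default [default_channels()] (58 scalp +
#'   VEOG + HEOG).
#' @param p3,evoked_alpha,induced_alpha,noise,artifacts,behavior Named lists
#'   overriding individual component parameters; see Details.
#' @param seed Master seed; all randomness derives from it via per-stream
#'   sub-seeds.
#'
#' @details Component defaults: P3 latency 353/405 ms (SD 44/50), amplitude
#' 8/6 uV (SD 2) at a Pz-focused topography, width 120 ms FWHM. Evoked
#' alpha: 10 Hz, fixed phase 0, burst center 146/151 ms (SD 15), 100 ms
#' FWHM (a few alpha cycles), 1.5 uV, PO6-focused. Induced alpha: 10 Hz,
#' uniform per-trial phase, ongoing amplitude 2 uV, trough 168/198 ms
#' (SD 40), depth 0.5, 200 ms FWHM (desynchronization evolves over a few
#' hundred ms, which is also the temporal resolution a 5 Hz-wide band-pass
#' can convey), same topography. Noise: 1/f with exponent 1, 10 uV RMS on scalp, 5 uV on the
#' bipolar EOG channels. Artifacts: blink rate
#' 0.3/trial, 250 uV / 120 ms FWHM blink pulses on VEOG with frontal-maximal
#' propagation to scalp; HEOG steps of 80 uV on 5% of trials. Behavior:
#' RT 384/447 ms, accuracy 99.55/99.51%.
#'
#' @return Object of class `SimulationParams`.
#' @export
simulation_params <- function(n_subjects = 26, n_trials_per_condition = 140,
                              sampling_rate = 500,
                              epoch_window = c(-200, 1000),
                              channels = default_channels(),
                              p3 = list(), evoked_alpha = list(),
                              induced_alpha = list(), noise = list(),
                              artifacts = list(), behavior = list(),
                              seed = 1L) {
  merge_defaults <- function(user, defaults, field) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown ", field, " parameter(s): ",
           paste(unknown, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  p <- list(
    n_subjects = n_subjects,
    n_trials_per_condition = n_trials_per_condition,
    sampling_rate = sampling_rate,
    epoch_window = epoch_window,
    channels = channels,
    conditions = c("ST", "DT"),
    p3 = merge_defaults(p3, list(
      latency_mean = c(ST = 353, DT = 405), latency_sd = c(ST = 44, DT = 50),
      latency_range = c(250, 600),
      amplitude = c(ST = 8, DT = 6), amplitude_sd = 2,
      width_ms = 120, focus = "Pz", spread = 2.5), "p3"),
    evoked_alpha = merge_defaults(evoked_alpha, list(
      frequency = 10, burst_center = c(ST = 146, DT = 151), center_sd = 15,
      center_range = c(100, 220), burst_width_ms = 100, amplitude = 1.5,
      phase = 0, focus = "PO6", spread = 2.5), "evoked_alpha"),
    induced_alpha = merge_defaults(induced_alpha, list(
      frequency = 10, amplitude = 2,
      trough_latency = c(ST = 168, DT = 198), latency_sd = 40,
      latency_range = c(110, 330), depth = 0.5, width_ms = 200,
      focus = "PO6", spread = 2.5), "induced_alpha"),
    noise = merge_defaults(noise, list(exponent = 1, rms = 10,
                                       eog_rms = 5), "noise"),
    artifacts = merge_defaults(artifacts, list(
      blink_rate = 0.3, blink_amplitude = 250, blink_width_ms = 120,
      heog_amplitude = 80, heog_fraction = 0.05), "artifacts"),
    behavior = merge_defaults(behavior, list(
      rt_mean = c(ST = 384, DT = 447), rt_subject_sd = 50, rt_resid_sd = 30,
      acc_mean = c(ST = 99.55, DT = 99.51), acc_sd = c(ST = 1.21, DT = 1.33)),
      "behavior"),
    seed = as.integer(seed))
  validate_simulation_params(p)
  class(p) <- "SimulationParams"
  p
}

validate_simulation_params <- function(p) {
  fail <- function(field, msg) stop("invalid parameter '", field, "': ", msg,
                                    call. = FALSE)
  if (!is.numeric(p$n_subjects) || p$n_subjects < 1)
    fail("n_subjects", "must be >= 1")
  if (!is.numeric(p$n_trials_per_condition) || p$n_trials_per_condition < 1)
    fail("n_trials_per_condition", "must be >= 1")
  if (p$sampling_rate <= 0) fail("sampling_rate", "must be > 0")
  if (!(p$epoch_window[1] < 0 && p$epoch_window[2] > 0))
    fail("epoch_window", "must span stimulus onset (start < 0 < end)")
  if (anyDuplicated(p$channels)) fail("channels", "duplicate labels")
  for (f in c("p3$amplitude", "evoked_alpha$amplitude",
              "induced_alpha$amplitude", "noise$rms",
              "artifacts$blink_amplitude", "artifacts$heog_amplitude")) {
    v <- eval(parse(text = paste0("p$", f)))
    if (any(v < 0)) fail(f, "amplitudes must be >= 0")
  }
  if (p$induced_alpha$depth < 0 || p$induced_alpha$depth > 1)
    fail("induced_alpha$depth", "depth fraction must be in [0, 1]")
  for (f in c("evoked_alpha$frequency", "induced_alpha$frequency")) {
    v <- eval(parse(text = paste0("p$", f)))
    if (v < 8 || v > 13) fail(f, "alpha frequency must be in [8, 13] Hz")
  }
  if (p$artifacts$heog_fraction < 0 || p$artifacts$heog_fraction > 1)
    fail("artifacts$heog_fraction", "must be a fraction in [0, 1]")
  invisible(TRUE)
}

epoch_times <- function(p) {
  fs <- p$sampling_rate
  k0 <- round(p$epoch_window[1] * fs / 1000)
  k1 <- round(p$epoch_window[2] * fs / 1000) - 1
  (k0:k1) * 1000 / fs
}

# 1/f-shaped noise: one big column-FFT over all (channel x trial) signals.
pink_noise <- function(nsamp, nsig, fs, exponent, rms) {
  if (rms == 0) return(matrix(0, nsamp, nsig))
  w <- matrix(stats::rnorm(nsamp * nsig), nsamp, nsig)
  if (exponent == 0) return(w * rms)
  k <- 0:(nsamp - 1)
  f <- pmin(k, nsamp - k) * fs / nsamp
  s <- c(0, f[-1]^(-exponent / 2))
  s <- s / sqrt(mean(s^2))
  x <- Re(stats::mvfft(stats::mvfft(w) * s, inverse = TRUE) / nsamp)
  x * rms
}

rtrunc_norm <- function(n, mean, sd, range) {
  pmin(pmax(stats::rnorm(n, mean, sd), range[1]), range[2])
}

#' Simulate one subject x condition epoch set
#'
#' @param params A [simulation_params()] object.
#' @param subject Subject index (1-based).
#' @param condition `"ST"` or `"DT"`.
#' @return List with `epochs` (an [epoch_set()]) and `truth` (the latent
#'   values drawn for this subject/condition; envelope latencies are reported
#'   at the argmax/argmin of the generating envelope on the sample grid).
#' @export
simulate_subject <- function(params, subject, condition) {
  stopifnot(inherits(params, "SimulationParams"))
  stopifnot(condition %in% params$conditions)
  p <- params
  times <- epoch_times(p)
  tsec <- times / 1000
  nsamp <- length(times)
  nch <- length(p$channels)
  ntr <- p$n_trials_per_condition
  fs <- p$sampling_rate
  is_eog <- p$channels %in% eog_channels()
  i_veog <- match("VEOG", p$channels)
  i_heog <- match("HEOG", p$channels)

  with_seed(split_seed(p$seed, "subject", subject, condition), {
    # --- latent per-subject draws -------------------------------------
    lat_p3 <- rtrunc_norm(1, p$p3$latency_mean[[condition]],
                          p$p3$latency_sd[[condition]], p$p3$latency_range)
    amp_p3 <- max(0, stats::rnorm(1, p$p3$amplitude[[condition]],
                                  p$p3$amplitude_sd))
    cen_ev <- rtrunc_norm(1, p$evoked_alpha$burst_center[[condition]],
                          p$evoked_alpha$center_sd,
                          p$evoked_alpha$center_range)
    lat_in <- rtrunc_norm(1, p$induced_alpha$trough_latency[[condition]],
                          p$induced_alpha$latency_sd,
                          p$induced_alpha$latency_range)

    # --- deterministic (phase-locked) waveforms -----------------------
    sig_p3 <- p$p3$width_ms / 2.355
    wave_p3 <- amp_p3 * exp(-(times - lat_p3)^2 / (2 * sig_p3^2))
    ea <- p$evoked_alpha
    sig_ev <- ea$burst_width_ms / 2.355
    env_ev <- exp(-(times - cen_ev)^2 / (2 * sig_ev^2))
    wave_ev <- ea$amplitude * env_ev *
      cos(2 * pi * ea$frequency * (tsec - cen_ev / 1000) + ea$phase)
    ia <- p$induced_alpha
    sig_in <- ia$width_ms / 2.355
    env_in <- 1 - ia$depth * exp(-(times - lat_in)^2 / (2 * sig_in^2))

    topo_p3 <- topography_weights(p$channels, p$p3$focus, p$p3$spread)
    topo_ev <- topography_weights(p$channels, ea$focus, ea$spread)
    topo_in <- topography_weights(p$channels, ia$focus, ia$spread)
    prop <- blink_propagation_factors(p$channels)

    # --- trial-varying draws ------------------------------------------
    phi <- stats::runif(ntr, 0, 2 * pi)
    noise_flat <- pink_noise(nsamp, nch * ntr, fs, p$noise$exponent,
                             p$noise$rms)
    # bipolar periocular derivations largely cancel distant cortical
    # sources: EOG channels carry less background noise than scalp
    if (p$noise$rms > 0 && any(is_eog)) {
      sc <- p$noise$eog_rms / p$noise$rms
      eog_cols <- as.vector(outer(which(is_eog), (seq_len(ntr) - 1) * nch,
                                  `+`))
      noise_flat[, eog_cols] <- noise_flat[, eog_cols] * sc
    }
    blink_trials <- which(stats::runif(ntr) < p$artifacts$blink_rate)
    blink_t <- stats::runif(length(blink_trials), times[1] + 150,
                            times[nsamp] - 150)
    heog_n <- round(p$artifacts$heog_fraction * ntr)
    heog_trials <- if (heog_n > 0) sort(sample.int(ntr, heog_n)) else integer(0)
    heog_onset <- stats::runif(heog_n, 0, times[nsamp] - 100)
    heog_sign <- sample(c(-1, 1), heog_n, replace = TRUE)

    # --- assemble: trials x channels x samples ------------------------
    arr <- array(aperm(array(noise_flat, c(nsamp, nch, ntr)), c(3, 2, 1)),
                 c(ntr, nch, nsamp))
    locked <- outer(topo_p3, wave_p3) + outer(topo_ev, wave_ev)  # ch x samp
    osc <- vapply(seq_len(ntr), function(i)
      ia$amplitude * env_in * sin(2 * pi * ia$frequency * tsec + phi[i]),
      numeric(nsamp))                                            # samp x trial
    for (i in seq_len(ntr))
      arr[i, , ] <- arr[i, , ] + locked + outer(topo_in, osc[, i])

    if (!is.na(i_veog) && length(blink_trials)) {
      sig_b <- p$artifacts$blink_width_ms / 2.355
      for (j in seq_along(blink_trials)) {
        pulse <- p$artifacts$blink_amplitude *
          exp(-(times - blink_t[j])^2 / (2 * sig_b^2))
        i <- blink_trials[j]
        arr[i, , ] <- arr[i, , ] + outer(prop, pulse)
        arr[i, i_veog, ] <- arr[i, i_veog, ] + pulse
      }
    }
    if (!is.na(i_heog) && heog_n > 0) {
      for (j in seq_len(heog_n)) {
        step <- heog_sign[j] * p$artifacts$heog_amplitude *
          (times >= heog_onset[j])
        arr[heog_trials[j], i_heog, ] <-
          arr[heog_trials[j], i_heog, ] + step
      }
    }

    truth <- list(
      subject = subject, condition = condition,
      p3_latency_ms = lat_p3, p3_amplitude_uv = amp_p3,
      evoked_center_ms = times[which.max(env_ev)],
      induced_trough_ms = times[which.min(env_in)],
      induced_depth_uv = ia$depth * ia$amplitude,
      blink_trials = blink_trials,
      heog_trials = heog_trials,
      blink_propagation = prop)

    list(epochs = epoch_set(arr, times, p$channels, condition = condition,
                            subject_id = sprintf("S%02d", subject)),
         truth = truth)
  })
}

#' Simulate the full study
#'
#' Generates every subject x condition [epoch_set()] plus the ground truth
#' and a behavioral table (per-subject reaction time and accuracy by
#' condition, with a shared subject speed factor). For the full default
#' geometry this is a large object; pipeline code streams subjects through
#' [simulate_subject()] instead.
#'
#' @param params A [simulation_params()] object.
#' @param subjects Subject indices to generate (default all).
#' @return List with `subjects` (nested list `[[subject]][[condition]]` of
#'   epoch sets), `truth` (list of per subject x condition ground-truth
#'   records), `behavior` (data frame) and `params`.
#' @export
generate_dataset <- function(params, subjects = seq_len(params$n_subjects)) {
  stopifnot(inherits(params, "SimulationParams"))
  out <- list(); truth <- list()
  for (s in subjects) {
    out[[sprintf("S%02d", s)]] <- lapply(
      stats::setNames(params$conditions, params$conditions),
      function(cond) {
        r <- simulate_subject(params, s, cond)
        truth[[paste0("S", s, "_", cond)]] <<- r$truth
        r$epochs
      })
  }
  list(subjects = out, truth = truth,
       behavior = simulate_behavior(params, subjects), params = params)
}

#' Simulated behavioral table
#'
#' @param params A [simulation_params()] object.
#' @param subjects Subject indices.
#' @return Data frame: subject, condition, rt_ms, accuracy_pct.
#' @export
simulate_behavior <- function(params, subjects = seq_len(params$n_subjects)) {
  b <- params$behavior
  rows <- lapply(subjects, function(s) {
    with_seed(split_seed(params$seed, "behavior", s), {
      base <- stats::rnorm(1, 0, b$rt_subject_sd)
      data.frame(
        subject = sprintf("S%02d", s),
        condition = params$conditions,
        rt_ms = b$rt_mean[params$conditions] + base +
          stats::rnorm(2, 0, b$rt_resid_sd),
        accuracy_pct = pmin(100, stats::rnorm(2, b$acc_mean[params$conditions],
                                              b$acc_sd[params$conditions])),
        row.names = NULL)
    })
  })
  do.call(rbind, rows)
}

#' Write a simulated dataset as BrainVision fixtures
#'
#' Each subject x condition epoch set is written as a continuous BrainVision
#' triplet (trials concatenated back-to-back, one stimulus marker `S1` at
#' each trial's t = 0 sample) plus a single JSON sidecar with the ground
#' truth and geometry.
#'
#' @param dataset Result of [generate_dataset()].
#' @param path Directory to write into (created if needed).
#' @return Invisibly, the sidecar path.
#' @export
write_fixture <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- dataset$params
  pre <- sum(epoch_times(p) < 0)
  for (sid in names(dataset$subjects)) {
    for (cond in names(dataset$subjects[[sid]])) {
      e <- dataset$subjects[[sid]][[cond]]
      d <- dim(e$data)
      flat <- matrix(aperm(e$data, c(2, 3, 1)), nrow = d[2])  # ch x (samp*tr)
      onsets <- (seq_len(d[1]) - 1) * d[3] + pre + 1
      rec <- continuous_recording(flat, sampling_rate_of(e),
                                  e$channel_labels,
                                  data.frame(sample = onsets, label = "S1"))
      write_brainvision(rec, file.path(path, paste0(sid, "_", cond)))
    }
  }
  sidecar <- file.path(path, "ground_truth.json")
  jsonlite::write_json(
    list(n_subjects = p$n_subjects,
         subjects = names(dataset$subjects),
         conditions = p$conditions,
         n_trials_per_condition = p$n_trials_per_condition,
         sampling_rate = p$sampling_rate,
         epoch_window = p$epoch_window,
         seed = p$seed,
         truth = dataset$truth,
         behavior = dataset$behavior),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
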