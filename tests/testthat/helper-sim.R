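# Shared fixtures: small simulation profiles used across test files.
# The reduced channel set keeps the posterior alpha focus (PO6), the P3
# focus (Pz), a frontal gradient for blink propagation, and both EOG
# channels.

small_channels <- function() {
  c("Fpz", "Fz", "Cz", "Pz", "PO5", "PO6", "Oz", "O2", "VEOG", "HEOG")
}

# grid montage needed whenever matrix_amplitudes / run_pipeline is involved
grid_channels <- function() c(t(electrode_matrix()), "VEOG", "HEOG")

small_params <- function(..., n_trials = 30, channels = small_channels(),
                         seed = 1) {
  simulation_params(n_subjects = 2, n_trials_per_condition = n_trials,
                    channels = channels, seed = seed, ...)
}

# component switches: everything off except what the test studies
quiet_overrides <- function() {
  list(p3 = list(amplitude = c(ST = 0, DT = 0), amplitude_sd = 0),
       evoked_alpha = list(amplitude = 0),
       induced_alpha = list(amplitude = 0),
       noise = list(rms = 0, eog_rms = 0),
       artifacts = list(blink_rate = 0, heog_fraction = 0))
}

# simulation with only the named components enabled at their defaults
params_with_only <- function(components, ..., n_trials = 30,
                             channels = small_channels(), seed = 1,
                             n_subjects = 2) {
  ov <- quiet_overrides()
  defaults <- list(
    p3 = list(), evoked_alpha = list(), induced_alpha = list(),
    noise = list(), artifacts = list())
  for (comp in components) ov[[comp]] <- defaults[[comp]]
  extra <- list(...)
  for (nm in names(extra))
    ov[[nm]] <- utils::modifyList(ov[[nm]] %||% list(), extra[[nm]])
  do.call(simulation_params,
          c(list(n_subjects = n_subjects,
                 n_trials_per_condition = n_trials,
                 channels = channels, seed = seed), ov))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
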