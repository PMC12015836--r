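Package: alphatse
Title: Evoked and Induced Alpha-Band EEG Dynamics via Temporal Spectral
    Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for separating phase-locked (evoked) and
    non-phase-locked (induced) alpha-band (8-13 Hz) activity in
    event-related EEG using the Temporal Spectral Evolution method:
    zero-phase Butterworth band-pass filtering, rectification, trial
    averaging and baseline correction, with the induced component
    obtained by subtracting the spectrally evoked response from the
    total. Includes a BrainVision reader/writer, regression-based
    ocular artifact correction, HEOG-based trial rejection, Hilbert
    instantaneous-phase analysis with circular statistics, P3 and
    alpha peak/mean-amplitude measurement on a 6 x 7 electrode matrix,
    a repeated-measures ANOVA layer with Greenhouse-Geisser correction
    and partial eta squared, and a ground-truth synthetic EEG
    generator emulating a two-condition (single- vs double-target)
    go/no-go study so that every stage of the pipeline is verifiable
    without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
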