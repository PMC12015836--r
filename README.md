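# alphatse

Separating **evoked** (phase-locked) from **induced** (non-phase-locked)
alpha-band EEG activity with the Temporal Spectral Evolution (TSE) method,
for researchers analysing event-related oscillatory dynamics — e.g. the
posterior alpha desynchronization that accompanies target detection under
varying cognitive load.

For epochs $x_i(t)$ and a zero-phase order-8 Butterworth band-pass $B$ over
8–13 Hz ("48 dB/octave"):

```
evoked(t)  = | B[ mean_i x_i ](t) |            # filter the ERP, rectify
total(t)   = mean_i | B[x_i](t) |              # filter + rectify each trial, average
induced(t) = total(t) - evoked(t)              # non-phase-locked remainder
```

with both traces baseline-corrected over −100…0 ms before the subtraction.
Phase-locked activity survives averaging and lands in `evoked`; amplitude
modulations of ongoing (random-phase) oscillations cancel from the average
and land in `induced` — for ongoing alpha of amplitude $A$, `total` sits at
the rectified-sinusoid mean $2A/\pi$. The package wraps this core in the
full pipeline of a two-condition (single-target/double-target go/no-go)
experiment:

* BrainVision (`.vhdr`/`.vmrk`/`.eeg`) reader and writer;
* HEOG-based trial rejection (strictly exceeding ±50 µV), regression-based
  blink correction with audited propagation factors, common average
  reference;
* P3 and alpha peak-latency / mean-amplitude measurement in the canonical
  windows (350–410, 140–155, 165–200 ms) at grand-average-selected
  electrodes (Pz, PO6), plus a 6 × 7 electrode-matrix amplitude table;
* Hilbert instantaneous-phase analysis with circular statistics (resultant
  length, Rayleigh test) demonstrating the evoked/induced dissociation;
* repeated-measures ANOVA with Greenhouse–Geisser correction and partial
  η², Shapiro–Wilk gating, paired *t* / Wilcoxon signed-rank, Bonferroni;
* a ground-truth synthetic-data generator emulating the study design
  (26 subjects × 2 conditions × 140 trials, 58 + 2 channels, 500 Hz,
  −200…1000 ms epochs) so every stage is verifiable end to end.

## Worked example

Simulate and analyse a 10-subject study (60 trials per condition; the full
26 × 140 design runs the same way, just longer):

```r
library(alphatse)
cfg <- list(seed = 42, n_subjects = 10, n_trials_per_condition = 60)
res <- run_pipeline(cfg, out_dir = "tse_run")
```

`tse_run/report.txt` then contains (this run's actual output, abridged):

```
Behavior
  RT (ms): ST 356.5 +/- 42.0, DT 437.8 +/- 54.0
  wilcoxon_signed_rank: statistic = -2.650, p = 0.008045, n = 10

P3 latency
  paired_t: statistic = -3.195, p = 0.01092, n = 10

Alpha latency grand means: evoked 145 ms, induced 179 ms
Alpha latency ANOVA (load x activity)
  condition            F(1, 9) =    0.257, eps = 1.000, p_gg = 0.6245, pes = 0.028
  activity             F(1, 9) =  108.277, eps = 1.000, p_gg = 2.568e-06, pes = 0.923
  condition:activity   F(1, 9) =    0.145, eps = 1.000, p_gg = 0.7118, pes = 0.016
```

Reading it: reaction time is slower under higher load (Wilcoxon Z = −2.65),
the P3 peaks later in the double-target condition (paired t), and the alpha
layer reproduces the signature pattern the pipeline is built around — the
evoked burst peaks earlier (145 ms) than the induced desynchronization
(179 ms), a large *activity* effect (partial η² = 0.92), while cognitive
load leaves alpha latency unaffected. The run directory also holds the
measurement tables, grand-average traces, per-subject phase summaries with
Rayleigh tests, and a manifest with the seed and config hash; re-running
the same config reproduces every file bit-identically.

Individual stages are ordinary functions (`simulate_subject()`,
`reject_heog()`, `correct_blinks()`, `tse_decompose()`, `phase_at_window()`,
`rm_anova()`, …) — see the vignette in `vignettes/alpha-tse-methods.Rmd`
for the model, parameter rationale and known limitations. A thin CLI lives
at `inst/cli/alphatse.R`.

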