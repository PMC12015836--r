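---
title: "Separating evoked and induced alpha activity with Temporal Spectral Evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating evoked and induced alpha activity with Temporal Spectral Evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphatse)
```

## The problem

Stimulus-related changes in alpha-band (8–13 Hz) EEG come in two flavours.
*Evoked* activity is phase-locked to the stimulus: it survives averaging
across trials and can therefore be computed from the event-related potential
(ERP). *Induced* activity is time-locked but not phase-locked — an amplitude
modulation of ongoing oscillations, most prominently the event-related
desynchronization (ERD) of posterior alpha — and it cancels in the trial
average. The two have different generators and different functional
interpretations, so an analysis that conflates them conflates mechanisms.

`alphatse` implements the Temporal Spectral Evolution (TSE) decomposition of
alpha activity into these components, together with the surrounding pipeline
of a two-condition (single-target vs double-target, ST/DT) visual go/no-go
experiment: BrainVision I/O, ocular artifact handling, P3 and alpha
latency/amplitude measurement on a 6 × 7 posterior-to-frontal electrode
matrix, Hilbert-phase analysis, and a repeated-measures statistical layer.
A synthetic-data generator with exact ground truth makes every stage
verifiable without access to real recordings.

## The decomposition

For epochs $x_i(t)$, $i = 1 \dots n$ (microvolts, one channel shown), with
$B$ the zero-phase alpha band-pass:

* **evoked** trace: $e(t) = \left| B\!\left[\tfrac1n \sum_i x_i\right](t)
  \right|$ — filter the ERP, full-wave rectify;
* **total** trace: $T(t) = \tfrac1n \sum_i \left| B[x_i](t) \right|$ —
  filter and rectify each trial, then average;
* **induced** trace: $I(t) = T(t) - e(t)$.

Both $e$ and $T$ are baseline-corrected over −100…0 ms before the
subtraction, so $I + e = T$ holds at machine precision by construction, and
$e \le T$ pointwise before baseline correction (Jensen's inequality:
$|\text{mean}| \le \text{mean}|\cdot|$). For ongoing alpha of amplitude $A$
with uniformly random phase per trial, $T \to 2A/\pi$ as $n \to \infty$ — the
mean of a rectified sinusoid — which gives the package an exact analytic
check of the whole chain.

Before filtering, each trial's pre-stimulus DC mean (−200…0 ms) is
subtracted. This matters for an exact reason: a DC offset is not annihilated
by a band-pass at epoch edges, and if only the ERP were baselined the two
branches would disagree at the 10⁻⁶ µV level even on identical trials.
Per-trial pre-stimulus baselining keeps the branches algebraically
commutable.

## The filter

"48 dB/octave" is read as the one-pass asymptotic rolloff at
6 dB/octave/pole, i.e. an order-8 Butterworth band-pass. The design goes
through the pole–zero route (analog prototype poles → band-pass s-plane
transform → bilinear transform with prewarping, using the `signal`
package's `Zpg` tools) and is executed as a cascade of eight second-order
sections with evenly distributed gain: the equivalent order-16
transfer-function polynomial, with a passband at 3–5 % of Nyquist, is
numerically fragile, while the biquad cascade reproduces the analytic
Butterworth magnitude to 10⁻¹⁰ (`filter_response()` exposes both). The
filter runs forward–backward (zero net phase: a symmetric pulse keeps its
peak sample), which squares the magnitude response; that doubling is
accepted as part of "zero-phase". Edges are handled by odd-reflection
padding of three low-edge periods (≈ 190 samples at 500 Hz), and the −200 ms
pre-stimulus segment buffers the remaining edge ring.

Time conventions: the epoch window is half-open $[t_0, t_1)$ — at 500 Hz,
−200…1000 ms is exactly 600 samples with stimulus onset on a sample — while
printed analysis windows (350–410, 140–155, 165–200 ms) are closed on both
ends with nearest-sample rounding. Latencies are reported on the 2 ms sample
grid without interpolation, ties broken to the earliest sample.

## The synthetic study

`simulation_params()` encodes the emulated design: 26 subjects × 2
conditions × 140 target trials, 58 scalp channels (10–10 names, including
the full 6 × 7 analysis grid) plus bipolar VEOG/HEOG, 500 Hz, epochs
−200…1000 ms. Each epoch sums:

* a **P3-like** midline-parietal positive wave (Gaussian, 120 ms FWHM),
  latency 353/405 ms (SD 44/50) and amplitude 8/6 µV (SD 2) for ST/DT;
* an **evoked alpha burst**: 10 Hz with the *same phase on every trial*,
  Gaussian envelope of 100 ms FWHM centred at 146/151 ms (SD 15), 1.5 µV,
  right parieto-occipital (PO6) topography;
* **induced alpha**: a 10 Hz oscillation with *uniform random phase per
  trial*, ongoing amplitude 2 µV, whose deterministic envelope carries a
  desynchronization trough (depth 0.5, 200 ms FWHM) at 168/198 ms (SD 40);
* **1/f noise** (exponent 1) at 10 µV RMS on scalp and 5 µV on the bipolar
  EOG channels — periocular bipolar derivations largely cancel distant
  cortical sources;
* **artifacts**: blinks at 0.3/trial (250 µV, 120 ms FWHM on VEOG,
  propagated to scalp by fixed frontal-maximal factors of 0.05–0.35) and
  80 µV HEOG step deflections on 5 % of trials.

Topographies are Gaussian weights on an idealized electrode grid — enough
to make Pz the P3 maximum and PO6 the alpha maximum, with no claim to
forward-model realism. All randomness derives from one seed through
per-stream sub-seeds, so identical parameters reproduce bit-identical data
and individual modules can be exercised in isolation.

Three default choices deserve their rationale:

* **Envelope widths (200/100 ms FWHM).** An 8–13 Hz band-pass has ≈ 5 Hz of
  bandwidth and therefore ≈ 200 ms of temporal resolution. Envelope
  features much faster than that put their modulation spectrum outside the
  band — a 40 ms (2.5-cycle) burst, for instance, simply cannot transit the
  filter. The defaults describe modulations the method can in principle
  convey, which is also the physiologically typical time scale of alpha
  ERD and evoked bursts.
* **Ongoing alpha as a fixed-frequency sinusoid** (not narrowband noise)
  keeps $2A/\pi$ exact for analytic verification; latent latency SDs
  (15/40 ms) are deliberately smaller than the between-subject spreads a
  study would *report*, because reported spreads fold in measurement noise
  on top of subject variability.
* **Blink model.** A positive VEOG pulse propagated by fixed per-channel
  factors gives the regression correction a known target. The correction
  estimates factors by pooled least squares on *average-subtracted*
  residuals (so event-related activity cannot leak into the estimate
  through chance covariance with blink timing) and then subtracts
  $b \cdot \mathrm{VEOG}$ from the raw channels. In the pipeline it runs
  before re-referencing — a common average reference would fold the mean
  blink topography into every factor. With zero noise the factors are
  recovered exactly; at the default SNR a session-pooled fit (both
  conditions, 280 trials) recovers them within ±0.02 of the generating
  fractions, the scale on which we state recovery (a relative ±2 % on the
  smallest occipital factors of ≈ 0.05 would demand blink energy beyond
  plausible blink rates).

What passing tests on these data do **not** show: robustness to narrowband
(non-sinusoidal) alpha, to topographic overlap of distinct sources, to
non-stationary noise, or to real ocular dynamics; the generator is a
verification harness, not a head model.

## Phase analysis

To demonstrate that the induced modulation is genuinely non-phase-locked,
the trial average is subtracted from each trial (leaving a data set whose
average is identically zero), the residuals are band-passed, and the
Hilbert transform — the FFT analytic-signal construction — supplies
instantaneous phase and envelope. Phases are summarized per trial by the
*circular* mean over the analysis window (phase wraps; arithmetic means are
meaningless), trials with window-mean envelope below 0.05 µV are excluded
(the phase of a near-zero analytic signal is noise), and concentration
across trials or subjects is quantified by the resultant vector length
$R$ with the Rayleigh test. The Rayleigh test is an addition of this
package: it turns "phases look randomly distributed on the polar plot" into
a quantitative statement ($R$ below $\sqrt{-\ln 0.05 / n}$, test
non-significant).

## Measurement and statistics

Latency and mean amplitude are extracted in the fixed windows (P3 350–410;
evoked alpha 140–155; induced alpha 165–200 ms) at the electrode with the
largest grand-average window extremum (ocular channels excluded; the
simulated topographies yield Pz and PO6), or at electrodes fixed in the
configuration. The induced measure defaults to the extremum of largest
absolute deviation (`"abs"`), with `"max"`/`"min"` available — a decrement
and a positive rebound are both legitimate readings of an induced window,
and the choice is a config key, not an assertion.

The statistical layer mirrors the study design: Shapiro–Wilk as a normality
gate; paired *t* or Wilcoxon signed-rank (normal approximation with tie and
continuity corrections — reported as a Z statistic) for paired contrasts;
and a fully within-subject repeated-measures ANOVA for the 2 × 6 × 7
amplitude designs and the 2 × 2 latency design. The ANOVA uses the
univariate approach with orthonormalized effect contrasts: for effect
scores $S$ ($n \times q$), $SS_\text{eff} = n\,\|\bar S\|^2$ with
$q$ numerator df, the subject-by-effect error $SS_\text{err}$ with
$q(n-1)$ df, Greenhouse–Geisser
$\hat\varepsilon = \mathrm{tr}(\Sigma)^2 / (q\,\mathrm{tr}(\Sigma^2))$
from the contrast covariance $\Sigma$ (bounded in $[1/q, 1]$; always 1 for
two levels), corrected p-values from the $\varepsilon$-scaled F
distribution, and partial $\eta^2 = SS_\text{eff}/(SS_\text{eff} +
SS_\text{err})$. Two identities anchor the arithmetic: for a two-level
factor, $F = t^2$ of the paired *t*-test (to 10⁻⁸ in tests), and partial
$\eta^2$ can be recomputed from any reported $F(1, n{-}1)$ as
$F/(F + n - 1)$ — which reproduces the reference study's printed effect
sizes (0.365 from $F = 14.362$, 0.252 from $F = 8.408$) exactly at three
decimals. Grand latency summaries are the unweighted mean of the two
condition means rounded half-up (149 ms from 146/151; 183 ms from
168/198). Bonferroni adjustment is $\min(1, m p)$. One caveat the tests
encode: the Greenhouse–Geisser correction is conservative
($p_{GG} \ge p$) in the region that matters, but for $F$ far below 1 the
df scaling can nudge a far-from-significant p slightly downward; this is a
property of the correction itself, shared by standard implementations
(cross-checked against `car::Anova` to 10⁻⁸).

## Pipeline and reproducibility

`run_pipeline()` drives generate → reject (|HEOG| strictly exceeding
50 µV; mask-based, never destructive) → blink-correct → re-reference →
decompose → measure → phase → report from one validated configuration
(`validate_config()`: defaults filled, unknown keys rejected, violations
listed field by field). Subjects are streamed one at a time — a full-size
epoch array is ~40 MB per subject and condition, and only traces and
measurement rows are retained. Numeric tables are written with `%.17g`
so a report rebuilt from cached stage outputs is bit-identical to one built
in memory; the stage cache is keyed by an MD5 hash of the normalized
configuration, so changing any analysis parameter (say `band_hz`)
invalidates it. A thin command-line wrapper lives at
`inst/cli/alphatse.R`.

```{r, eval = FALSE}
cfg <- list(seed = 1, n_subjects = 26, n_trials_per_condition = 140)
res <- run_pipeline(cfg, out_dir = "tse_run")
res$report$alpha_latency$grand_ms
```

Test and verification problem sizes were chosen to exercise the study
geometry where it matters (140 trials wherever an invariant depends on
$1/\sqrt{n}$ cancellation; 26 subjects for ensemble properties; 2 000
replicates for type-I calibration) and reduced channel montages elsewhere.

## Known limitations

* **Evoked–induced interaction.** The subtraction is linear but
  rectification is not: where a phase-locked burst of amplitude $b$ rides
  on random-phase alpha of amplitude $A$, the total trace behaves like
  $\tfrac2\pi\,\mathrm{E}\,|b + A e^{i\varphi}|$, which is *less* than
  $\tfrac2\pi(b + 2A/\pi)$ — so the induced trace acquires a spurious dip
  at the burst latency even in noise-free data. A test demonstrates the
  effect deliberately. Conclusions about induced timing near a strong
  evoked burst should be drawn cautiously.
* **Latency resolution.** The band-pass flattens envelope extrema
  (σ ≈ 70–85 ms after filtering), so grid-argmax latencies of single-subject
  traces jitter by tens of ms at realistic noise levels; rectification
  ripple at $2f$ quantizes evoked-trace peaks in ≈ 24–48 ms steps unless
  smoothed. Between-subject latency spreads of 70–95 ms in induced measures
  are thus expected even when the underlying subject variability is half
  that. Noise-free data recover latencies exactly (tested), and the
  deterministic dense-phase limit localizes the ERD trough on the
  generating envelope's argmin; per-subject peak latencies at realistic
  SNR should be treated as noisy measurements, not point estimates.
* The rectified traces are not smoothed by default; classical TSE variants
  often low-pass after rectification, and a cycle-scale moving average
  removes the $2f$ ripple but not the plateau jitter above.
* The blink correction is a single-channel regression stand-in validated
  only against the synthetic ground truth; it is not an implementation of
  any published multi-source ocular correction, and ICA-based removal is
  out of scope.
* Only stimulus-onset markers, target epochs and the alpha band are
  modelled; BrainVision support covers the IEEE float-32 and int-16 binary
  dialects (multiplexed or vectorized), nothing else.
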