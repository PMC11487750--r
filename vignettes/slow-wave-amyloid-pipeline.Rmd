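---
title: "From sleep EEG to amyloid accumulation: methods and design choices"
author: "swamyloid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sleep EEG to amyloid accumulation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swamyloid)
```

This vignette documents the models and procedures the package implements,
the tunable parameters and why their defaults are what they are, what the
synthetic generators do and do not emulate, and the numerical decisions made
where the method description left room.

## 1. The measurement model

Each participant contributes a split-night polysomnogram (a diagnostic
portion followed by a PAP titration portion, stages scored per 30-s epoch)
and two PiB-PET scans. The pipeline reduces these to one row per participant
and portion:

* **Relative spectral power.** On the Fz–Cz derivation, each non-artifact
  30-s epoch gets a Welch power spectral density; power is integrated over
  seven bands (SO 0.5–0.9, delta 1–3.9, theta 4–7.9, alpha 8–11.9, sigma
  12–14.9, beta 15–29.9, low gamma 30–35 Hz, closed intervals as printed,
  with the small inter-band gaps assigned to no band) and expressed as a
  percentage of the seven-band total, so the seven values sum to 100 per
  epoch. Participant summaries are unweighted means over NREM (N1–N3)
  epochs of a portion; an N3-only summary is offered and requires at least
  30 eligible N3 epochs (15 min), below which it is reported missing.

* **Slow-wave downslopes.** On the Fz–earlobe-average derivation, the signal
  is bandpass filtered 0.5–35 Hz (2000-tap Hamming-window FIR, applied
  forward–backward so the net phase shift is zero) and smoothed with a 50-ms
  moving average. Descending zero-crossings are located with linear
  interpolation; each candidate wave is classed SO or delta by the
  separation of its bounding crossings, its trough is the global minimum
  between them (earliest sample on ties), waves with troughs above −5 µV are
  discarded, and the downslope is |trough|/(t_trough − t_crossing) in µV/s,
  stored as a positive magnitude. Slopes are averaged within each epoch and
  the epoch means are averaged over NREM epochs with at least one detection
  (a detection-weighted pooling is available via `weight_by_count`).

* **Amyloid accumulation.** Global SUVR is the (optionally weighted) mean of
  six amyloid-susceptible ROIs. The outcome is the annualized log-scale
  change (ln s₂ − ln s₁)/Δt, computed identically per ROI; the centiloid
  scale is the affine map CL = 100·((−0.1620 + 0.9467·S) − 1.009)/1.067, and
  the centiloid rate is the difference of converted values per year (not the
  conversion of the log rate). Baseline amyloid positivity is SUVR ≥ 1.48,
  boundary inclusive.

* **Association stage.** Linear models of annualized accumulation on
  z-scored exposures (sample SD, n−1 denominator) with classical t-based
  inference; backward elimination drops the eligible covariate with the
  largest partial-F p-value while it exceeds 0.1 (for single-df terms the
  partial-F p equals the t-test p, which the implementation uses); exposures
  are forced into the model and never eliminated. Collinearity is checked
  with variance inflation factors (diagonal of the inverse predictor
  correlation matrix; two predictors correlated at 0.88 give VIF = 4.43,
  below the ≤5 bar). Paired diagnostic-vs-titration comparisons use the
  paired t-test and Cohen's d = mean(diff)/sd(diff); sd(diff) is the sample
  SD of differences, which already carries the correlation adjustment since
  sd(diff)² = s₁² + s₂² − 2·r·s₁·s₂. Predictions at feature quantiles
  evaluate the linear predictor at sample quantiles of one feature with all
  other terms held at a caller-stated profile — the profile is a required
  argument, not a hidden default, because no single convention (means vs
  reference categories) is universally right. No multiplicity correction is
  applied by default (`adjust_p()` offers Benjamini–Hochberg). Subgroup
  analyses by amyloid status are plain refits on the filtered table, with
  no interaction term.

## 2. Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Epoch length | 30 | s | Standard sleep-scoring grid; fixed. |
| Sampling rate | 500 | Hz | Clinical PSG export rate; the filter length (2000 taps) and 50-ms smoother (25 samples) are defined relative to it. Other rates are accepted; `resample_signal()` converts when desired. |
| Bandpass | 0.5–35, 2000 taps, Hamming | Hz | The stated detection-path design; applied forward–backward for zero phase. |
| Smoother | 0.05 | s | 50-ms centered boxcar with shrinking edges. |
| SO / delta duration windows | 1.1–2 / 0.25–1.0 | s | Separation of bounding crossings; see §4 for which crossings. |
| Amplitude threshold | −5 | µV | Trough must reach it (inclusive); chosen for sensitivity in older adults with low-amplitude slow waves. |
| Welch segments | 8, overlap 0.5 | s | See §4. |
| N3-only minimum | 30 epochs | — | 15 min of N3 representation. |
| Artifact rules | |x| > 250 µV or flat > 5 s | — | Explicit, overridable; external flags are respected. |
| Removal threshold | 0.1 | — | Probability of F for removal in backward elimination. |
| PiB+ cutoff | 1.48 | SUVR | Baseline positivity, inclusive. |

## 3. The synthetic generators

`synthesize_recording()` builds EEG as a per-stage mixture of components:
continuous sinusoids (for spectral oracles — their band powers are A²/2 and
the relative split is exact), windowed multi-cycle sinusoid trains at a
stated events/min density (for detection oracles — each injected event is
recorded with its analytic downslope 4·A·f, and events are countable), and
band-limited Gaussian noise plus a 1/f noise floor (for realism and
robustness tests). Reference channels carry no signal so both derivations
recover the mixture. The default night is a two-cycle diagnostic-portion
architecture with roughly 168 min of sleep at stage shares near N1 25%,
N2 48%, N3 16%, REM 11%; component amplitudes were chosen once so that a
simulated night summarizes near the descriptive values typical of older
adults with OSA (NREM SO% in the mid-20s, delta% in the high 30s, SO-slope
≈ 90 µV/s, delta-slope ≈ 134 µV/s). Two constraints shaped those choices:
a pure tone's slope and power are coupled (slope = 4·A·f), so delta-band
power comes from dense 1.5 Hz trains rather than high-amplitude ones; and
broadband background is placed at 15–30 Hz, where the 50-ms smoother
suppresses its influence on trough depths.

What the generator does **not** emulate: K-complexes and spindles, the
within-night homeostatic decay of SWA (testable by rescaling, as the test
suite does), respiratory-event coupling, non-stationary artifacts, or
reference-channel activity. Passing oracle tests therefore demonstrates
algorithmic correctness on signals with known structure, not clinical
validity on real EEG.

`synthesize_cohort()` draws the four SWA features from a correlated
Gaussian (r = 0.88 within the slope pair, −0.45 within the percentage pair,
the pairs independent of each other — the cross-pair correlation is not
documented for the population of interest, so it is left at zero), ages,
*APOE* ε4 carriage, and baseline SUVR from a lognormal whose ≥1.48 tail
gives ~39% positivity. The outcome is the stated linear model on the
annualized log-SUVR scale (per-SD effects 0.0033, 0.0003, 0.0069, −0.0082
for SO%, delta%, SO-slope, delta-slope; covariate effects 0.0005/yr of age,
0.004 for ε4, 0.0104 for baseline positivity; residual SD 0.010, chosen so
the total outcome SD lands near the observed 0.013), and follow-up SUVR is
derived from baseline, outcome and interval so the PET stage reconstructs
the outcome exactly. Generating parameters are returned alongside the data;
coverage tests compare fitted confidence intervals against them.

## 4. Numerical decisions

**Duration-window reading.** Taken literally, "negative half-waves whose
zero-crossings are separated by 1.1–2 s" describes waves of 0.25–0.45 Hz,
inconsistent with the 0.5–0.9 Hz SO band; read as the separation of
successive *descending* crossings (the full-wave period), 1.1–2 s is
0.5–0.91 Hz and 0.25–1.0 s is 1–4 Hz, matching the bands exactly. The
period criterion is the default; the literal half-wave criterion is
available via `criterion = "halfwave"`.

**Spectral path is unfiltered by default.** The band integration itself
confines the analysis to 0.5–35 Hz, and the 2000-tap design's lower
transition lies *inside* the SO band: its forward–backward gain is 0.40 at
0.5 Hz and 0.87 at 0.7 Hz, which would cut SO power by roughly a quarter
and shift a 50/50 SO/alpha tone split to about 43/57. Relative PSD is
therefore computed on the raw derivation (with per-segment mean removal in
Welch handling drift); `prefilter = TRUE` restores filtering first. The
detection path keeps the filter: slope estimates tolerate its edge response
(the recovered slope of a 98 µV/s oracle train stays within 5%).

**Welch parameters.** 8-s Hamming segments with 50% overlap give 0.125 Hz
bins, so the 0.4-Hz-wide SO band spans several bins and the Hamming main
lobe of sub-hertz components stays inside the band; with 4-s segments a
0.7 Hz tone leaks ~5% of its power into the 1.0 Hz bin and the delta band.
`segment_sec = 30, overlap = 0` yields a single-taper periodogram.

**Crossing times and troughs.** Crossing instants are linearly interpolated
(sample-level timing would quantize slope denominators by 2 ms at 500 Hz);
troughs are the global minimum between bounding crossings, earliest sample
on ties; waves straddling an epoch boundary belong to the epoch containing
the trough; the −5 µV threshold applies to the smoothed detection signal.
No extra demeaning precedes crossing detection: after the 0.5 Hz high-pass
the mean is already ≈0.

**Zero phase.** The linear-phase FIR is applied forward–backward (squared
magnitude response, zero phase); a single pass with group-delay
compensation is available (`single_pass = TRUE`). Filtering runs once over
the continuous recording before epoching, via FFT convolution with zero
edge extension, so per-epoch edge transients never arise.

**Degenerate inputs.** All-zero epochs yield undefined relative PSD (NA,
epoch marked missing); empty NREM selections and under-represented N3
return missing summaries with reason codes; identical paired vectors return
the null effect (d = 0) while a constant non-zero shift errors (zero SD of
differences); rank-deficient designs error naming the aliased terms;
standardizing a constant errors.

**EDF.** 16-bit EDF with per-channel physical scaling over the full int16
range; round trips are exact to one quantization step. Signals are
zero-padded to whole data records on write (with a warning). The header
rate is always passed through; resampling is explicit, never implicit.

## 5. Problem sizes in the test suite

Unit oracles run on 30–120 s signals at 500 Hz; the detection acceptance
check simulates a 30-min N3 night; coverage checks use 200 cohorts of
n = 64 (the SWA-analysis sample size); the reproducibility check runs the
full simulate → EDF/TSV → features → cohort → associate chain twice on a
6-min recording and compares outputs bit for bit. These sizes were chosen
so the full suite completes in well under a minute while every Monte-Carlo
assertion retains a comfortable margin over its sampling error.

## 6. Known limitations

* Single-derivation analysis: no travelling-wave or global-vs-local slow
  wave distinction, no multi-channel coherence.
* EDF+ discontinuous records and the EDF+ annotation byte stream are not
  parsed; stage annotations can be supplied as an (onset, duration, stage)
  table via `hypnogram_from_annotations()`, which maps them to the 30-s
  grid by majority stage.
* The synthetic EEG is schematic (see §3); spectral leakage aside, real
  EEG's broadband 1/f structure means band percentages on real data depend
  on the background spectrum in ways the oracles do not probe.
* ROI weights for the global SUVR default to equal weights; if volumes are
  available they should be passed explicitly.
* Classical (non-robust) standard errors throughout, consistent with the
  effect-size reconstructions in the test suite.
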