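# swamyloid

Sleep slow-wave activity features and longitudinal amyloid-PET accumulation.

## The problem

Non-REM slow-wave activity (SWA) — the synchronized cortical up/down-state
activity of deep sleep — has been implicated in amyloid-β clearance, and its
disruption in obstructive sleep apnoea (OSA) is a candidate link between OSA
and Alzheimer's-disease pathology. Testing that link requires connecting two
very different measurements per participant:

1. **Polysomnographic EEG** (split-night studies: a diagnostic portion, then
   a PAP titration portion), from which SWA is quantified per 30-s epoch as

   - *relative spectral power* in the slow-oscillation (SO, 0.5–0.9 Hz) and
     delta (1–3.9 Hz) bands, expressed as the percentage of summed power over
     seven bands (SO, delta, theta 4–7.9, alpha 8–11.9, sigma 12–14.9, beta
     15–29.9, low gamma 30–35 Hz); and
   - *slow-wave downslopes*: negative half-waves are detected on the smoothed
     Fz–earlobe signal by zero-crossings, classed SO vs delta by duration
     windows (crossings separated by 1.1–2 s and 0.25–1.0 s respectively,
     trough ≤ −5 µV), and each wave's downslope is
     `|trough amplitude| / (t_trough − t_zero-crossing)` in µV/s.

2. **Two-timepoint PiB-PET**, summarized as annualized log-scale amyloid
   accumulation `ΔPiB(log)/yr = (ln SUVR₂ − ln SUVR₁) / Δt`, the centiloid
   conversion `CL = 100·((−0.1620 + 0.9467·SUVR) − 1.009)/1.067`, and
   baseline amyloid positivity (SUVR ≥ 1.48).

The association stage fits per-SD standardized linear models of annualized
accumulation on the SWA features, adjusted for baseline age, *APOE* ε4 and
baseline amyloid status, with backward elimination (probability of F for
removal 0.1), variance-inflation-factor collinearity checks, subgroup refits
by amyloid status, paired diagnostic-vs-titration comparisons with Cohen's
*d* for paired samples (`d = mean(diff)/sd(diff)`), and model predictions at
feature quartiles.

`swamyloid` implements the whole chain as a tidy, pipeable R package — EDF
and hypnogram I/O, feature extraction, PET annualization and the statistical
procedures — together with seeded synthetic EEG and cohort generators whose
ground truth is known analytically (a sinusoidal slow wave of amplitude *A*
and frequency *f* has downslope `4·A·f`), so every stage of the pipeline can
be tested against an oracle.

## Worked example

Simulate a diagnostic-portion recording, extract participant-level SWA
features, and fit the association model on a synthetic cohort:

```r
library(swamyloid)

sim <- synthesize_recording(psg_spec(
  stage_sequence = data.frame(stage = c("N1", "N2", "N3", "N2", "R"),
                              n_epochs = c(14, 26, 9, 1, 6)),
  seed = 42))
extract_swa_features(sim$recording, sim$hypnogram)
#>   so_pct delta_pct so_slope delta_slope   (columns 3:6)
#> 1   29.4      34.9     83.9       130.6

co <- synthesize_cohort(cohort_spec(seed = 42))$cohort
fit <- fit_ols(co, "delta_pib_log_yr",
               c("so_slope", "delta_slope", "age", "apoe4", "pib_status"),
               standardize = c("so_slope", "delta_slope"))
fit
#> <swa_ols> delta_pib_log_yr ~ so_slope + delta_slope + age + apoe4 + pib_status  (n = 64, adj. R^2 = 0.441)
#>   term         estimate std.error statistic   p.value   conf.low conf.high   vif
#> 1 (Intercept) -0.0585    0.0156       -3.76 0.000402  -0.0896     -0.0273  NA
#> 2 so_slope     0.00533   0.00269       1.98 0.0520    -0.0000467   0.0107   3.40
#> 3 delta_slope -0.00976   0.00270      -3.61 0.000636  -0.0152     -0.00435  3.43
#> 4 age          0.000801  0.000211      3.80 0.000351   0.000379    0.00122  1.10
#> 5 apoe4        0.00639   0.00326       1.96 0.0550    -0.000140    0.0129   1.09
#> 6 pib_status   0.0139    0.00310       4.48 0.0000356  0.00769     0.0201   1.06
```

The feature row is the participant's mean SWA over NREM epochs of the
diagnostic portion: SO contributes ~29% of spectral power, delta ~35%, and
the mean downslopes are ~84 and ~131 µV/s. In the model, each slope
coefficient is the change in annualized log-SUVR accumulation per 1 SD of
that feature (here the generating effects were +0.0069 for SO-slope and
−0.0082 for delta-slope); the VIF column shows the slope pair stays below
the ≤5 collinearity bar despite their high mutual correlation. `tidy()`,
`glance()` and `autoplot()` work on fitted objects; `backward_eliminate()`,
`correlate()`, `paired_compare()` and `predict_at_quantiles()` cover the
rest of the procedure. A command-line front end over the same functions is
in `inst/cli/swamyloid.R`.

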