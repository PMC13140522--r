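# nirstfa

Transfer function analysis of dynamic cerebral autoregulation (dCA) from
simultaneous arterial blood pressure (ABP) and near-infrared spectroscopy
(NIRS) recordings, as used to monitor stroke patients during endovascular
treatment (EVT) under general anaesthesia.

**Who it is for.** Physiologists and clinical researchers who record a
continuous ABP waveform alongside multichannel prefrontal NIRS (long 35 mm
channels per hemisphere plus a 10 mm short-separation channel) and want
band-averaged autoregulation measures and mixed-model statistics — and
methodologists who want a fully synthetic, ground-truth-controlled test bed
for that pipeline.

## The method

For an ABP input $x(t)$ and an oxygenated-haemoglobin (OxyHb) output
$y(t)$, the package estimates the Welch cross-spectral transfer function

$$H(f) = \frac{S_{xy}(f)}{S_{xx}(f)}, \qquad
\gamma^2(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)},$$

and reports gain $|H|$ (µM·mm/mmHg), normalized gain (%/%), squared
coherence $\gamma^2$, and phase $\arg H$ in degrees — **positive when OxyHb
follows ABP, negative when it precedes ABP** — averaged over the VLF
(0.02–0.07 Hz), LF (0.07–0.2 Hz) and HF (0.2–0.5 Hz) bands. Around the
estimator sit the stages a real recording needs:

* synthetic recording generator with exact band-wise transfer-function
  ground truth, scalp (extracerebral) contamination, artifacts, vitals and
  event markers (`synthesize_recording()`);
* modified Beer–Lambert conversion of two-wavelength optical densities
  (`mbll_convert()`, `forward_mbll()`);
* artifact flagging + linear interpolation, ABP beat detection,
  beat-to-beat averaging and 10 Hz resampling (`flag_artifacts()`,
  `detect_beats()`, `beat_average_resample()`);
* steady-state 5-minute segment selection with anaesthesia-induction and
  drug-change exclusion zones and a 10% vitals-variation rule
  (`select_segments()`);
* Welch TFA, band averaging, and the 180° single-channel phase consistency
  correction (`compute_tfa()`, `band_average()`, `correct_phase_wrap()`);
* paired side-to-side tests, Benjamini–Hochberg adjustment, and linear
  mixed models of LF phase with a subject random intercept and a
  short-separation-channel regressor (`paired_side_test()`,
  `fdr_adjust()`, `fit_phase_lmm()` with `tidy()`/`glance()`).

`run_pipeline()` chains everything on one recording. See the methods
vignette (`vignettes/dca-tfa-methods.Rmd`) for the model, parameter
defaults, and design rationale.

## Worked example

```r
library(nirstfa)
library(dplyr)

rec <- synthesize_recording(synth_config(duration_s = 1800, seed = 42))
rec
#> <nirs_recording> 1800 s @ 50 Hz, 8 NIRS channels, 5 events

select_segments(rec, segment_criteria(), masks = "auto")[, 1:3]
#>   label start_s end_s
#> 1   PRE     360   660
#> 2  POST     890  1190
#> 3    2H    1500  1800

res <- run_pipeline(rec)
res |>
  filter(band == "LF", segment == "POST", hemisphere == "ischaemic") |>
  select(channel, role, gain, normalized_gain, phase_deg, coherence)
#>   channel  role gain normalized_gain phase_deg coherence
#> 1   IH_L1  long 9.18            7.34      47.7     0.737
#> 2   IH_L2  long 9.18            7.34      47.7     0.737
#> 3   IH_L3  long 9.18            7.34      47.7     0.737
#> 4   IH_S1 short 6.58            5.27      79.9     0.306
```

The recording was generated with a true LF gain of 10 µM·mm/mmHg and a true
LF phase of +40°; the long (cortical) channels recover gain ≈ 9.2 and phase
≈ 48° under 20% scalp contamination with coherence ≈ 0.74, while the
short (scalp) channel shows the low coherence expected of a mostly
extracerebral signal. The three PRE/POST/2H windows respect the 5-min
post-induction and 2-min post-drug-change exclusions (induction at 60 s,
drug change at 770 s) and the 2H window sits as late as possible.

The statistical stage, on a simulated 38-subject cohort with an
ischaemic-hemisphere ETCO2 sensitivity of −26.7 °/kPa:

```r
tab <- synthesize_subject_table(subject_sim_spec(
  n_subjects = 38, seed = 7,
  etco2_slope_deg_per_kpa = c(ischaemic = -26.7, contralateral = 0)))

paired_side_test(tab)[, c("method", "n_pairs", "estimate", "p_value")]
#>          method n_pairs estimate p_value
#> 1 paired t-test      38    0.119   0.982

fit <- fit_phase_lmm(tab, fixed = "etco2")
tidy(fit)[, c("term", "estimate", "conf_low", "conf_high", "p_value")]
#>                        term estimate conf_low conf_high p_value
#> 1               (Intercept)  83.9670  -18.199   186.134   0.106
#> 2       hemisphereischaemic  37.6591  -87.178   162.497   0.545
#> 3                     etco2 -10.1013  -31.622    11.420   0.352
#> 4              ss_phase_deg  -0.0976   -0.438     0.242   0.567
#> 5 hemisphereischaemic:etco2  -8.0990  -34.666    18.468   0.541
```

The mean hemispheric difference is near zero (no hemisphere effect was
simulated), and the hemisphere × ETCO2 interaction estimate carries a wide
single-dataset confidence interval that covers the simulated −26.7 °/kPa;
the test suite verifies ≥ 92% coverage over 500 such simulations.

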