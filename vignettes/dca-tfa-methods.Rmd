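---
title: "Assessing dynamic cerebral autoregulation from ABP and NIRS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing dynamic cerebral autoregulation from ABP and NIRS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirstfa)
library(dplyr)
```

## The problem

Dynamic cerebral autoregulation (dCA) keeps cerebral blood flow roughly
constant while arterial blood pressure (ABP) fluctuates on a time scale of
seconds to a minute. In the frequency domain this behaves like a high-pass
filter: slow ABP oscillations — in particular the ~0.1 Hz Mayer waves — are
damped and phase-advanced in the cerebral circulation, while faster
oscillations pass through. Transfer function analysis (TFA) between a
continuous ABP waveform and a cerebral perfusion surrogate quantifies this
with three spectral measures: gain (amplitude ratio), phase shift, and
squared coherence, band-averaged over the very-low (VLF, 0.02–0.07 Hz),
low (LF, 0.07–0.2 Hz) and high (HF, 0.2–0.5 Hz) frequency bands.

The perfusion surrogate here is oxygenated haemoglobin (OxyHb) measured by
near-infrared spectroscopy (NIRS) on the prefrontal cortex, a montage that
is practical during endovascular stroke treatment (EVT) under general
anaesthesia where transcranial Doppler is not. Each hemisphere carries
three long (35 mm source–detector) channels that see cortex plus scalp, and
one short (10 mm) channel that sees essentially only scalp; the short
channel's TFA result later serves as a nuisance regressor in the
statistical models, since no preprocessing step can fully remove
extracerebral contamination from the long channels.

The sign convention for phase is fixed throughout the package: **positive
phase means the OxyHb oscillation follows (occurs after) the ABP
oscillation; negative phase means OxyHb precedes ABP.** A pure transport
delay of $\tau$ seconds therefore yields $+360 f \tau$ degrees at frequency
$f$, and this is pinned by a test.

No clinical recordings ship with the package. Every stage is exercised on
synthetic recordings with exact, configurable ground truth, which is what
makes the pipeline testable end to end.

## The synthetic recording generator

`synthesize_recording()` builds, on one clock:

* **ABP**: a pulsatile carrier (three harmonics of the heart rate with
  relative amplitudes 1 / 0.4 / 0.15, scaled to a configurable pulse
  pressure), a Mayer-wave sinusoid at `lfo_freq_hz` (default 0.1 Hz,
  2 mmHg), a respiratory component (0.25 Hz), a band-limited (0.02–0.5 Hz)
  stochastic fluctuation, and optional white noise. The broadband component
  matters: spontaneous haemodynamic activity is not a line spectrum, and it
  gives every in-band frequency bin genuine input power so that
  band-averaged estimates are well defined.
* **NIRS channels**: the ABP signal passed through an exact frequency-domain
  transfer function — per hemisphere and band a configured gain
  (µM·mm/mmHg) and phase (package sign convention), out-of-band content
  passing with unit gain and zero phase — then mixed with a shared scalp
  oscillation so that a configurable fraction of the fluctuation variance
  is extracerebral (default 0.2 for long channels, 0.9 for short channels),
  plus optional drift and noise.
* **Artifacts**: additive square pulses with a recorded ground-truth mask,
  placed one per equal time block with 10 s margins (discrete patient
  movements do not abut in practice, and separated events keep the
  detection problem well posed).
* **Vitals** (HR, SpO2, ETCO2, mean ABP at 1 Hz) with baselines anchored at
  a stroke-EVT cohort under general anaesthesia (HR 63 bpm, SpO2 99%,
  ETCO2 4.6 kPa, MAP 80 mmHg), configurable drift and square excursions;
  and **event markers** (anaesthesia induction, first recanalization
  attempt, final reperfusion status, drug changes, anaesthesia
  termination).

Identical configuration and seed give bit-identical output. Ground truth —
the scalp component, artifact masks, beat onset times (the maximum-upstroke
point of the pulse shape in each cycle), and the transfer table — travels
with the recording in its `truth` element.

The generator emulates the statistical structure the analysis assumes: a
linear, stationary ABP→OxyHb relationship per band, steady vitals outside
scheduled excursions, and additive artifacts. It does **not** emulate
nonstationary autoregulation, nonlinear or multivariate (CO2-driven)
coupling, realistic pulse morphology, or recanalization haemodynamics —
passing tests therefore demonstrate correctness of the estimation
machinery, not physiological validity on real data.

The default LF transfer (gain 10 µM·mm/mmHg, phase +40°) places the
simulated LF phase near the ~40° typically observed for ABP–OxyHb coupling
after recanalization; subject-level simulation defaults
(`subject_sim_spec()`) use LF phase 40 ± 22° residual spread, age
69.6 ± 13.9 y, ETCO2 4.59 ± 0.45 kPa, and an optional ischaemic-hemisphere
ETCO2 sensitivity of −26.7 °/kPa, mirroring the magnitudes reported for
EVT cohorts — as generator settings, not reproduction claims.

## Preprocessing

**Beer–Lambert conversion.** Raw two-wavelength optical-density changes are
inverted per sample through the modified Beer–Lambert law. Output stays in
pathlength-scaled units (µM·mm) — dividing by an assumed partial pathlength
would inject an unmeasured constant. The default extinction table
(Gratzer/Kollias values at 760/850 nm, as distributed with the Homer
toolchains) and DPF = 1 are explicit configuration: devices and vendors
differ, and the package never treats these constants as ground truth.
Recordings already converted by vendor software enter the pipeline directly.

**Artifact handling.** Detection is deterministic and two-pronged: (i) a
robust z-score of the residual from a running-median baseline (5 s window),
using a 95 %-quantile-consistent scale estimate — a plain MAD underestimates
the spread of narrowband physiological residuals and produced false
positives on scalp-dominated channels; (ii) sharp edges in the first
difference are paired, and the span between two consecutive opposite-signed
edges closer than `max_gap_s` is flagged, which captures square artifacts
and isolated spikes exactly. Flagged samples are repaired by linear
interpolation between the nearest clean neighbours (edge runs filled with
the nearest value); runs longer than `max_gap_s` are reported as
unsalvageable. Interpolation is idempotent and touches no clean sample.

**Beat averaging and resampling.** Beat onsets are found on ABP by
maximum-upstroke detection (local maxima of the first derivative, accepted
greedily by slope under a 0.3 s refractory period). Each signal — OxyHb
channels included, on the single ABP-derived beat grid, so input and output
stay exactly aligned — is averaged over each inter-onset interval, the mean
placed at the interval midpoint, and linearly interpolated onto a uniform
10 Hz grid. Midpoint placement plus linear interpolation is the simplest
convention; since both TFA inputs undergo the same operation, the small
sinc-type attenuation of in-band oscillations cancels in gain and phase
(verified to 0.1°/0.4% by the recovery sweep).

## Steady-state segment selection

Analysis windows are 5 min. A window is admissible when

* it does not overlap the 5 min after anaesthesia induction or the 2 min
  after any drug-change marker;
* every monitored vital (HR, mean ABP, SpO2, ETCO2) varies by at most 10%
  within the window, measured as (max − min) / window mean — the reference
  for "10% variation" is a design choice, documented and configurable;
* the artifact-flag density on every signal stays below 5%.

Windows are scanned at 1 s stride. PRE (induction → first recanalization
attempt) and POST (final reperfusion status → anaesthesia termination) take
the **earliest** admissible window; the post-anaesthesia segment (2H,
termination → 2 h after recanalization) takes the **latest**, favouring
maximal recovery time. The scan-order rule makes ties impossible. An
exhaustive 1 s brute-force scan over all candidate windows is the test
oracle for this whole module. Whether all vitals must satisfy the rule
simultaneously (they must, here) and whether PRE should prefer the earliest
or the best-quality window are genuinely open conventions; both are
criteria settings, not claims about any particular study's choices.

## Transfer function analysis

`compute_tfa()` implements Welch cross-spectral estimation from scratch
(the estimator is the scientific core of the package): overlapping Hann
windows (default 100 s, 50% overlap, per-window mean removal),
averaged auto- and cross-spectra, $H(f) = S_{xy}/S_{xx}$, gain $|H|$,
coherence $|S_{xy}|^2/(S_{xx}S_{yy})$, and phase mapped to the package
sign convention on the principal interval (−180°, 180°]. The defaults
follow standard autoregulation-TFA practice and are fully configurable;
with 5-min segments they give five windows and 0.01 Hz resolution, so VLF
holds 5 bins and LF 13. A single rectangular window with mean removal
reduces the estimator exactly to the direct DFT cross-spectrum, which is
asserted at 1e-10 relative tolerance.

Band averaging takes the arithmetic mean of gain, coherence and the PSDs
over in-band bins; phase is averaged **circularly**, weighted by
cross-spectral magnitude — the averaging rule for phase is not standardized,
and magnitude weighting suppresses noise-dominated bins without gating.
No coherence threshold gates the reported estimates by default (estimates
and coherence are reported side by side); a critical-coherence filter can
be applied by the caller.

Normalized gain (% output change per % input change) is
`gain × mean_input / output_scale`. The output scale must be supplied by
the caller (the pipeline default is 100 µM·mm): OxyHb *change* signals have
near-zero means, so a percent-of-mean normalization is ill-defined, and the
package refuses to guess one implicitly.

**180° consistency correction.** Low in-band amplitude occasionally flips a
single channel's estimated phase by an accurate 180° against the other
channels of the same hemisphere. When exactly one channel deviates from the
circular mean of the remaining channels by 180 ± 30° while those remaining
(at least two) agree within 30°, the deviant is shifted by 180° toward the
group and flagged; any other configuration — including two deviants — is
left untouched. Full 360° wrap-around is handled by principal-value
mapping throughout.

## Statistics

The per-segment, per-band rows feed three analyses:

* **Paired side-to-side tests** (`paired_side_test()`): per-subject
  ischaemic-minus-contralateral differences, Shapiro–Wilk screen at
  α = 0.05 choosing between a paired t-test and the Wilcoxon signed-rank
  test. Exactly constant differences short-circuit to a documented
  degenerate result (p reported as 0 for a nonzero offset).
* **Benjamini–Hochberg adjustment** (`fdr_adjust()`) for families of
  sequential comparisons; the family definition (all pairwise segment
  contrasts per measure) is a documented convention.
* **Linear mixed models** (`fit_phase_lmm()`): REML fits with a subject
  random intercept; fixed effects are hemisphere, the requested covariates,
  hemisphere-by-covariate interactions, the short-separation-channel phase
  as nuisance regressor, and — for sequential models — time segment with
  segment-by-covariate and segment-by-hemisphere interactions. Categorical
  fixed effects with any level under 4 subjects are refused rather than
  silently fitted. Convergence warnings are captured and surfaced, and
  unidentifiable designs (one observation per subject) raise an error
  rather than crash.

Inference uses Satterthwaite denominator degrees of freedom (via lmerTest)
for t- and type-III F-tests; confidence intervals are Wald-type
`estimate ± t(df)·SE`. Satterthwaite was chosen over containment /
between-within approximations because it is the de-facto standard
companion of lme4 in R and is well calibrated at these sample sizes —
Monte-Carlo checks in the test suite put the type-I error of the hemisphere
effect at n = 38 within 5 ± 1.5 percentage points and the 95% CI coverage of
a hemisphere-by-ETCO2 interaction above 92%. `glance()` reports
Nakagawa–Schielzeth marginal and conditional R² (fixed-effect variance over
total; fixed plus random over total), AIC, variance components, and the
singularity/convergence status.

## Numerical choices and degenerate inputs

* Phase principal interval (−180°, 180°]; the wrap point maps to +180°.
* Coherence is clipped to ≤ 1 against floating-point overshoot; bins with
  zero input power return `NA` rather than spurious ratios.
* Welch needs at least one full window; fewer raises an error naming the
  window length.
* The Beer–Lambert inversion refuses singular extinction matrices and
  non-positive DPFs; the artifact interpolator refuses all-flagged series;
  beat detection refuses flat or sub-10 s inputs.
* All simulation entry points take explicit integer seeds and restore the
  caller's RNG state.

## Problem sizes

Tests and the acceptance script run the generator at 400–1800 s per
recording (50 Hz waveforms), an 18-cell noiseless recovery sweep
(6 phases × 3 gains), 20 randomized recordings for the segment-selection
oracle, and Monte-Carlo calibration with 1000 paired-test and 500
mixed-model replicates at the cohort sizes the models target (n = 38
single-segment; n = 11 × 2 hemispheres × 3 segments sequential). These
sizes give Monte-Carlo standard errors comfortably inside the asserted
bands (e.g. ±0.7 pp on a 5% rejection rate at 1000 replicates).

## Known limitations

* The generator's Mayer wave is a sinusoid plus band-limited noise; the
  spectral shape of real spontaneous LFOs varies between patients and
  anaesthetic regimes, so absolute coherence levels on real data will
  differ from the synthetic ones.
* Short-separation regression enters at the statistical stage (as in the
  models this package targets), not as a time-series regression during
  preprocessing; the package does not attempt to quantify residual
  extracerebral sensitivity.
* Beat detection is tuned for arterial-line-quality waveforms; it is not
  an ECG replacement and has no arrhythmia handling beyond the refractory
  rule.
* SNIRF ingestion covers two-wavelength continuous-wave files with a
  single data block; frequency-domain or time-domain NIRS variants are out
  of scope.
* Reported clinical effect estimates from any particular cohort cannot be
  reproduced here, because no recordings are distributed; the package's
  claims are about the correctness and calibration of the machinery.
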