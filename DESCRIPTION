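Package: nirstfa
Title: Transfer Function Analysis of Dynamic Cerebral Autoregulation from
    NIRS and Arterial Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of dynamic cerebral autoregulation (dCA) from
    simultaneous arterial blood pressure (ABP) waveforms and near-infrared
    spectroscopy (NIRS) oxygenated-haemoglobin signals. Provides a synthetic
    recording generator with configurable band-wise ABP-to-OxyHb transfer
    functions and ground truth, modified Beer-Lambert conversion of raw
    optical densities, artifact interpolation, beat-to-beat averaging with
    10 Hz resampling, steady-state 5-minute segment selection around
    anaesthesia and drug-change events, Welch-based transfer function
    analysis (power spectral density, coherence, gain, normalized gain,
    phase shift in VLF/LF/HF bands) with single-channel 180-degree phase
    consistency correction, and a statistical stage with paired side-to-side
    tests, Benjamini-Hochberg adjustment, and linear mixed-effects models of
    low-frequency phase shift with a short-separation-channel regressor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
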