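#' Default band-wise ABP-to-OxyHb transfer functions
#'
#' One row per hemisphere and frequency band, giving the true gain
#' (µM·mm/mmHg) and true phase shift (degrees; positive = OxyHb follows ABP,
#' negative = OxyHb precedes ABP) that [synthesize_recording()] imposes on the
#' band-limited ABP component of every cerebral (long-channel) signal.
#' Defaults place the low-frequency (LF) phase near 40 degrees, the value
#' typically seen for ABP-to-OxyHb coupling in the prefrontal cortex, with a
#' gain of 10 µM·mm/mmHg.
#'
#' @param lf_gain,lf_phase_deg LF (0.07-0.2 Hz) gain and phase.
#' @param vlf_gain,vlf_phase_deg VLF (0.02-0.07 Hz) gain and phase.
#' @param hf_gain,hf_phase_deg HF (0.2-0.5 Hz) gain and phase.
#' @return A tibble with columns `hemisphere`, `band`, `gain_true`,
#'   `phase_true_deg`.
#' @export
default_band_transfer <- function(lf_gain = 10, lf_phase_deg = 40,
                                  vlf_gain = 15, vlf_phase_deg = 15,
                                  hf_gain = 5, hf_phase_deg = 20) {
  tidyr::expand_grid(
    hemisphere = c("ischaemic", "contralateral"),
    tibble(
      band = c("VLF", "LF", "HF"),
      gain_true = c(vlf_gain, lf_gain, hf_gain),
      phase_true_deg = c(vlf_phase_deg, lf_phase_deg, hf_phase_deg)
    )
  )
}

#' Configuration for a synthetic EVT monitoring recording
#'
#' Bundles every knob of the synthetic-recording generator. Defaults emulate
#' the intra-procedural monitoring conditions of endovascular stroke
#' treatment under general anaesthesia: heart rate near 63 bpm, mean ABP near
#' 80 mmHg, a 0.1 Hz Mayer-wave oscillation, a respiratory component, event
#' markers for anaesthesia induction, recanalization, a vasoactive drug
#' change, and anaesthesia termination, and steady vitals (HR, SpO2, ETCO2,
#' mean ABP) sampled at 1 Hz.
#'
#' @param duration_s Recording length in seconds. Must be at least 300 s
#'   (one 5-minute analysis window) and long enough to contain all events.
#' @param fs_raw Waveform sampling rate in Hz.
#' @param hr_bpm Heart rate, beats per minute.
#' @param hr_jitter_frac Fractional standard deviation of beat-to-beat period
#'   jitter (0 = perfectly periodic).
#' @param map_mmhg Mean arterial pressure baseline.
#' @param pulse_amplitude_mmhg Peak-to-peak amplitude of the pulsatile
#'   carrier (sum of three harmonics of `hr_bpm` with relative amplitudes
#'   1, 0.4, 0.15).
#' @param lfo_freq_hz,lfo_amplitude_mmhg Centre frequency and amplitude of
#'   the low-frequency (Mayer-wave) ABP oscillation.
#' @param abp_broadband_sd_mmhg Standard deviation of the band-limited
#'   (0.02-0.5 Hz) stochastic ABP fluctuation that accompanies the Mayer
#'   wave; spontaneous haemodynamic activity is broadband, and this
#'   component gives every analysis-band frequency bin genuine input power.
#' @param resp_freq_hz,resp_amplitude_mmhg Respiratory ABP component.
#' @param band_transfer Tibble as returned by [default_band_transfer()].
#' @param extracerebral_fraction Share of long-channel fluctuation variance
#'   contributed by the common scalp component, in `[0, 1]`.
#' @param short_extracerebral_fraction Same for short (10 mm) channels;
#'   defaults to 0.9 since short channels see mostly extracerebral tissue.
#' @param scalp_freq_hz Centre frequency of the shared scalp oscillation.
#' @param nirs_drift_per_h Linear drift added to every NIRS channel,
#'   µM·mm per hour.
#' @param noise_sd Named vector `c(abp = , nirs = )` of additive white-noise
#'   standard deviations (mmHg and µM·mm).
#' @param artifact_spec List `list(count, amplitude, duration_s)` describing
#'   additive square-pulse artifacts injected (with recorded ground-truth
#'   masks) into the ABP waveform and every NIRS channel.
#' @param event_times Named numeric vector of event-marker times in seconds.
#'   Recognised names: `ga_induction`, `recan_start` (first recanalization
#'   attempt), `recanalization` (final reperfusion status), `drug_change`
#'   (may repeat), `ga_termination`.
#' @param vitals_spec List with `baseline` (named vector `hr`, `spo2`,
#'   `etco2`, `map`), `noise_sd` (same names), `drift_per_s` (same names,
#'   linear drift), and optional `excursions` tibble with columns `vital`,
#'   `time_s`, `amplitude`, `duration_s` (square excursions).
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bit-identical recordings.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 1800,
                         fs_raw = 50,
                         hr_bpm = 63,
                         hr_jitter_frac = 0,
                         map_mmhg = 80,
                         pulse_amplitude_mmhg = 20,
                         lfo_freq_hz = 0.1,
                         lfo_amplitude_mmhg = 2,
                         abp_broadband_sd_mmhg = 1,
                         resp_freq_hz = 0.25,
                         resp_amplitude_mmhg = 1,
                         band_transfer = default_band_transfer(),
                         extracerebral_fraction = 0.2,
                         short_extracerebral_fraction = 0.9,
                         scalp_freq_hz = 0.08,
                         nirs_drift_per_h = 0,
                         noise_sd = c(abp = 0, nirs = 0),
                         artifact_spec = list(count = 0, amplitude = 30,
                                              duration_s = 2),
                         event_times = c(ga_induction = 60,
                                         recan_start = 700,
                                         recanalization = 750,
                                         drug_change = 770,
                                         ga_termination = 1200),
                         vitals_spec = default_vitals_spec(),
                         seed = 1L) {
  cfg <- list(
    duration_s = duration_s, fs_raw = fs_raw, hr_bpm = hr_bpm,
    hr_jitter_frac = hr_jitter_frac, map_mmhg = map_mmhg,
    pulse_amplitude_mmhg = pulse_amplitude_mmhg,
    lfo_freq_hz = lfo_freq_hz, lfo_amplitude_mmhg = lfo_amplitude_mmhg,
    abp_broadband_sd_mmhg = abp_broadband_sd_mmhg,
    resp_freq_hz = resp_freq_hz, resp_amplitude_mmhg = resp_amplitude_mmhg,
    band_transfer = band_transfer,
    extracerebral_fraction = extracerebral_fraction,
    short_extracerebral_fraction = short_extracerebral_fraction,
    scalp_freq_hz = scalp_freq_hz,
    nirs_drift_per_h = nirs_drift_per_h,
    noise_sd = noise_sd, artifact_spec = artifact_spec,
    event_times = event_times, vitals_spec = vitals_spec,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @export
default_vitals_spec <- function() {
  list(
    baseline = c(hr = 63, spo2 = 99, etco2 = 4.6, map = 80),
    noise_sd = c(hr = 0.4, spo2 = 0.15, etco2 = 0.03, map = 0.6),
    drift_per_s = c(hr = 0, spo2 = 0, etco2 = 0, map = 0),
    excursions = NULL
  )
}

validate_synth_config <- function(cfg) {
  if (cfg$duration_s < 300) {
    abort("`duration_s` must be at least 300 s (one 5-minute window).")
  }
  if (cfg$fs_raw < 50) abort("`fs_raw` must be at least 50 Hz.")
  freqs <- c(cfg$lfo_freq_hz, cfg$resp_freq_hz, cfg$scalp_freq_hz,
             3 * cfg$hr_bpm / 60)
  if (any(freqs >= cfg$fs_raw / 2)) {
    abort("All component frequencies must lie below the Nyquist rate fs_raw/2.")
  }
  for (f in c(cfg$extracerebral_fraction, cfg$short_extracerebral_fraction)) {
    if (f < 0 || f > 1) abort("Extracerebral fractions must lie in [0, 1].")
  }
  bt <- cfg$band_transfer
  need <- c("hemisphere", "band", "gain_true", "phase_true_deg")
  if (!is.data.frame(bt) || !all(need %in% names(bt))) {
    abort("`band_transfer` must have columns hemisphere, band, gain_true, phase_true_deg.")
  }
  if (!all(bt$band %in% c("VLF", "LF", "HF"))) {
    abort("Invalid band specification: bands must be VLF, LF or HF.")
  }
  if (any(bt$gain_true < 0)) abort("`gain_true` must be non-negative.")
  ev <- cfg$event_times
  if (length(ev) && any(ev < 0 | ev > cfg$duration_s)) {
    abort("`duration_s` too short for the requested event times.")
  }
  invisible(cfg)
}

# channel montage: three long (35 mm) + one short (10 mm) per hemisphere
channel_montage <- function() {
  tidyr::expand_grid(
    hemisphere = c("ischaemic", "contralateral"),
    tibble(
      ch = c("L1", "L2", "L3", "S1"),
      separation_mm = c(35, 35, 35, 10),
      role = c("long", "long", "long", "short"),
      territory = c("MCA-ACA border", "MCA-ACA border", "ACA", "extracerebral")
    )
  ) |>
    dplyr::mutate(
      channel = paste0(ifelse(.data$hemisphere == "ischaemic", "IH", "CH"),
                       "_", .data$ch),
      .before = 1
    ) |>
    dplyr::select(-"ch")
}

# phase offset (radians within the cycle) of the maximum upstroke of the
# 3-harmonic pulse shape; used as ground-truth beat onset
pulse_upstroke_phase <- function() {
  phi <- seq(0, 2 * pi, length.out = 20001)
  dshape <- -(sin(phi) + 0.8 * sin(2 * phi) + 0.45 * sin(3 * phi))
  phi[which.max(dshape)]
}

#' Generate a synthetic ABP + NIRS recording with known ground truth
#'
#' Builds an arterial blood pressure waveform (pulsatile carrier at the
#' configured heart rate plus Mayer-wave, respiratory and noise components),
#' derives each NIRS OxyHb channel by passing the band-limited ABP content
#' through the configured frequency-domain transfer function (exact gain and
#' phase per band; out-of-band content passes with unit gain and zero phase),
#' mixes in a shared extracerebral scalp component according to each
#' channel's role, injects square-pulse artifacts with a recorded mask, and
#' produces vitals traces and event markers.
#'
#' The returned object carries a `truth` element with the scalp component,
#' per-signal artifact masks, ground-truth beat onset times, and the
#' configured band transfer table, enabling exact downstream verification.
#'
#' @param config A [synth_config()].
#' @return An object of class `nirs_recording`: a list with tibbles `abp`
#'   (`time_s`, `abp_mmhg`), `nirs` (`time_s` plus one column per channel,
#'   µM·mm), `channels` (montage metadata), `vitals` (`time_s`, `hr_bpm`,
#'   `spo2_pct`, `etco2_kpa`, `map_mmhg`), `events` (`event`, `time_s`),
#'   scalars `fs_raw`, `vitals_fs`, and the `config` and `truth` lists.
#' @examples
#' rec <- synthesize_recording(synth_config(duration_s = 400, seed = 7))
#' rec
#' @export
synthesize_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  withr::local_seed(config$seed)

  n <- round(config$duration_s * config$fs_raw) + 1L
  t <- (seq_len(n) - 1L) / config$fs_raw
  period0 <- 60 / config$hr_bpm

  # beat grid (possibly jittered), spanning the recording
  n_beats <- ceiling(config$duration_s / period0) + 2L
  jit <- if (config$hr_jitter_frac > 0) {
    rnorm(n_beats, 0, config$hr_jitter_frac)
  } else {
    rep(0, n_beats)
  }
  periods <- period0 * pmax(0.5, 1 + jit)
  beat_t <- c(0, cumsum(periods))

  # instantaneous cardiac phase, piecewise linear across beats
  k <- findInterval(t, beat_t, rightmost.closed = FALSE)
  frac <- (t - beat_t[k]) / (beat_t[k + 1L] - beat_t[k])
  phi <- 2 * pi * (k - 1L + frac)

  shape <- cos(phi) + 0.4 * cos(2 * phi) + 0.15 * cos(3 * phi)
  ptp <- diff(range(cos(seq(0, 2 * pi, length.out = 4001)) +
                      0.4 * cos(2 * seq(0, 2 * pi, length.out = 4001)) +
                      0.15 * cos(3 * seq(0, 2 * pi, length.out = 4001))))
  carrier <- (shape - mean(shape)) * config$pulse_amplitude_mmhg / ptp

  lfo <- config$lfo_amplitude_mmhg * sin(2 * pi * config$lfo_freq_hz * t)
  resp <- config$resp_amplitude_mmhg * sin(2 * pi * config$resp_freq_hz * t)
  broad <- if (config$abp_broadband_sd_mmhg > 0) {
    config$abp_broadband_sd_mmhg *
      bandpass_noise(n, config$fs_raw, 0.02, 0.5)
  } else {
    0
  }
  abp_noise_sd <- unname(config$noise_sd["abp"] %|na|% 0)
  abp <- config$map_mmhg + carrier + lfo + resp + broad +
    (if (abp_noise_sd > 0) rnorm(n, 0, abp_noise_sd) else 0)

  # ground-truth beat onsets = maximum-upstroke times of the pulse shape
  up <- pulse_upstroke_phase() / (2 * pi)
  onset_t <- beat_t[-length(beat_t)] + up * periods
  onset_t <- onset_t[onset_t >= 0 & onset_t <= config$duration_s]

  # shared scalp component (unit-free oscillation + band-limited noise)
  scalp <- sin(2 * pi * config$scalp_freq_hz * t + runif(1, 0, 2 * pi)) +
    0.3 * lowpass_noise(n, config$fs_raw, cutoff_hz = 0.3)
  scalp_c <- scalp - mean(scalp)

  montage <- channel_montage()
  bands <- tfa_bands()
  nirs_noise_sd <- unname(config$noise_sd["nirs"] %|na|% 0)
  drift <- config$nirs_drift_per_h * t / 3600

  neuro_by_hemi <- lapply(
    setNames(unique(montage$hemisphere), unique(montage$hemisphere)),
    function(h) {
      bt <- config$band_transfer[config$band_transfer$hemisphere == h, ]
      apply_band_transfer(abp, config$fs_raw, bt, bands)
    }
  )

  nirs_vals <- list()
  masks <- list()
  for (i in seq_len(nrow(montage))) {
    ch <- montage$channel[i]
    neuro <- neuro_by_hemi[[montage$hemisphere[i]]]
    f <- if (montage$role[i] == "short") {
      config$short_extracerebral_fraction
    } else {
      config$extracerebral_fraction
    }
    neuro_c <- neuro - mean(neuro)
    x <- if (f <= 0) {
      neuro
    } else if (f >= 1) {
      mean(neuro) + scalp_c * sd(neuro_c) / sd(scalp_c)
    } else {
      mean(neuro) + sqrt(1 - f) * neuro_c +
        sqrt(f) * scalp_c * sd(neuro_c) / sd(scalp_c)
    }
    x <- x + drift
    if (nirs_noise_sd > 0) x <- x + rnorm(n, 0, nirs_noise_sd)
    art <- inject_artifacts(x, config$fs_raw, config$artifact_spec)
    nirs_vals[[ch]] <- art$signal
    masks[[ch]] <- art$mask
  }
  abp_art <- inject_artifacts(abp, config$fs_raw, config$artifact_spec)

  vit <- synth_vitals(config)
  events <- tibble(
    event = names(config$event_times),
    time_s = unname(config$event_times)
  )

  structure(
    list(
      abp = tibble(time_s = t, abp_mmhg = abp_art$signal),
      nirs = dplyr::bind_cols(tibble(time_s = t), as_tibble(nirs_vals)),
      channels = montage,
      vitals = vit,
      events = events,
      fs_raw = config$fs_raw,
      vitals_fs = 1,
      config = config,
      truth = list(
        scalp = scalp_c,
        beat_onset_s = onset_t,
        artifact_mask = c(list(abp = abp_art$mask), masks),
        band_transfer = config$band_transfer,
        clean_abp = abp
      )
    ),
    class = "nirs_recording"
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat("<nirs_recording> ", x$config$duration_s, " s @ ", x$fs_raw, " Hz, ",
      nrow(x$channels), " NIRS channels, ", nrow(x$events), " events\n",
      sep = "")
  invisible(x)
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

# unit-sd gaussian noise restricted to [f_lo, f_hi] via FFT masking
bandpass_noise <- function(n, fs, f_lo, f_hi) {
  z <- rnorm(n)
  Z <- fft(z)
  f <- fft_freqs(n, fs)
  Z[abs(f) < f_lo | abs(f) > f_hi] <- 0
  x <- Re(fft(Z, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

# smoothed gaussian noise, rough low-pass via FFT truncation
lowpass_noise <- function(n, fs, cutoff_hz) {
  z <- rnorm(n)
  Z <- fft(z)
  f <- fft_freqs(n, fs)
  Z[abs(f) > cutoff_hz] <- 0
  x <- Re(fft(Z, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

# two-sided FFT bin frequencies for length n at rate fs
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# exact per-band frequency-domain transfer: for bins with |f| in a band,
# multiply by gain * exp(-i * phase) (conjugate-symmetric), giving a reported
# phase of +phase_true_deg (output follows ABP) under the package convention
apply_band_transfer <- function(x, fs, bt, bands) {
  n <- length(x)
  f <- fft_freqs(n, fs)
  H <- rep(1 + 0i, n)
  for (j in seq_len(nrow(bt))) {
    b <- bands[bands$band == bt$band[j], ]
    sel <- abs(f) >= b$f_lo & abs(f) < b$f_hi
    th <- bt$phase_true_deg[j] * pi / 180
    H[sel] <- bt$gain_true[j] * exp(-1i * th * sign(f[sel]))
  }
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

# artifacts are placed one per equal time block with 10 s margins, so
# separate motion events never abut (physically, discrete patient movements)
inject_artifacts <- function(x, fs, spec) {
  n <- length(x)
  mask <- rep(FALSE, n)
  count <- spec$count %||% 0
  if (count > 0) {
    dur <- round((spec$duration_s %||% 2) * fs)
    block <- n / count
    margin <- 10 * fs
    starts <- vapply(seq_len(count), function(j) {
      lo <- max(1, round((j - 1) * block + margin))
      hi <- max(lo + 1, round(j * block - dur - margin))
      lo + sample.int(hi - lo + 1L, 1L) - 1L
    }, numeric(1))
    signs <- sample(c(-1, 1), count, replace = TRUE)
    for (j in seq_len(count)) {
      idx <- starts[j]:min(n, starts[j] + dur - 1L)
      x[idx] <- x[idx] + signs[j] * (spec$amplitude %||% 30)
      mask[idx] <- TRUE
    }
  }
  list(signal = x, mask = mask)
}

synth_vitals <- function(config) {
  vs <- config$vitals_spec
  tv <- seq(0, config$duration_s, by = 1)
  out <- tibble(time_s = tv)
  cols <- c(hr = "hr_bpm", spo2 = "spo2_pct", etco2 = "etco2_kpa",
            map = "map_mmhg")
  for (v in names(cols)) {
    x <- vs$baseline[[v]] + (vs$drift_per_s[[v]] %||% 0) * tv
    nsd <- vs$noise_sd[[v]] %||% 0
    if (nsd > 0) x <- x + rnorm(length(tv), 0, nsd)
    out[[cols[[v]]]] <- x
  }
  exc <- vs$excursions
  if (!is.null(exc) && nrow(exc) > 0) {
    for (j in seq_len(nrow(exc))) {
      col <- cols[[exc$vital[j]]]
      sel <- tv >= exc$time_s[j] & tv < exc$time_s[j] + exc$duration_s[j]
      out[[col]][sel] <- out[[col]][sel] + exc$amplitude[j]
    }
  }
  out
}
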