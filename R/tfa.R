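#' Standard autoregulation frequency bands
#'
#' Very-low (0.02-0.07 Hz), low (0.07-0.2 Hz) and high (0.2-0.5 Hz)
#' frequency bands used for band-averaged transfer function estimates.
#' Bands are half-open intervals `[f_lo, f_hi)`.
#'
#' @return Tibble with columns `band`, `f_lo`, `f_hi`.
#' @export
tfa_bands <- function() {
  tibble(band = c("VLF", "LF", "HF"),
         f_lo = c(0.02, 0.07, 0.2),
         f_hi = c(0.07, 0.2, 0.5))
}

#' Welch estimation parameters for transfer function analysis
#'
#' Defaults follow common transfer-function-analysis practice for
#' spontaneous-oscillation cerebral autoregulation studies: 100 s Hann
#' windows with 50% overlap and per-window mean removal.
#'
#' @param window_s Window length, seconds.
#' @param overlap_fraction Fractional overlap between windows.
#' @param taper `"hanning"` or `"none"` (rectangular).
#' @param detrend `"mean"` (per-window mean removal) or `"none"`.
#' @param bands Band table, see [tfa_bands()].
#' @return A list of class `tfa_params`.
#' @export
tfa_params <- function(window_s = 100, overlap_fraction = 0.5,
                       taper = c("hanning", "none"),
                       detrend = c("mean", "none"),
                       bands = tfa_bands()) {
  taper <- match.arg(taper)
  detrend <- match.arg(detrend)
  stopifnot(window_s > 0, overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 taper = taper, detrend = detrend, bands = bands),
            class = "tfa_params")
}

as_series <- function(x, value, fs) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(fs)) abort("`fs` is required for vector input.")
    list(values = x, fs = fs)
  } else {
    v <- x[[value]]
    f <- if (is.null(fs)) 1 / median(diff(x$time_s)) else fs
    list(values = v, fs = f)
  }
}

#' Welch cross-spectral transfer function estimate
#'
#' Estimates auto-spectra of the input (ABP) and output (OxyHb), their
#' cross-spectrum, and the derived transfer function from overlapping
#' tapered windows: \eqn{H(f) = S_{xy}(f)/S_{xx}(f)}, gain \eqn{|H|},
#' squared coherence \eqn{|S_{xy}|^2/(S_{xx} S_{yy})}, and phase shift in
#' degrees under the convention that a positive phase means the output
#' oscillation follows (occurs after) the ABP oscillation and a negative
#' phase means it precedes ABP. One-sided power spectral densities are
#' returned in (signal unit)^2/Hz.
#'
#' @param input,output Data frames with `time_s` and a value column, or
#'   numeric vectors sampled at `fs`. Both must have equal length and rate.
#' @param fs Sampling rate, Hz (required for vector input).
#' @param params A [tfa_params()].
#' @param input_value,output_value Value column names for data-frame input
#'   (default `"value"`).
#' @return A tibble of class `tfa_spectra` with columns `freq_hz`,
#'   `psd_input`, `psd_output`, `cross_re`, `cross_im`, `coherence`,
#'   `gain`, `phase_deg`; attributes `fs`, `n_windows`, `mean_input`,
#'   `mean_output`, `params`.
#' @examples
#' x <- sin(2 * pi * 0.1 * (0:2999) / 10) + rnorm(3000, 0, 0.1)
#' sp <- compute_tfa(x, 2 * x, fs = 10)
#' band_average(sp)
#' @export
compute_tfa <- function(input, output, fs = NULL, params = tfa_params(),
                        input_value = "value", output_value = "value") {
  xin <- as_series(input, input_value, fs)
  yout <- as_series(output, output_value, fs)
  if (abs(xin$fs - yout$fs) > 1e-9) abort("Input and output sampling rates differ.")
  x <- xin$values
  y <- yout$values
  if (length(x) != length(y)) abort("Input and output lengths differ.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("Series must be finite.")
  fs <- xin$fs

  nw <- round(params$window_s * fs)
  if (nw > length(x)) abort("Series shorter than one analysis window.")
  hop <- max(1L, round(nw * (1 - params$overlap_fraction)))
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  K <- length(starts)

  w <- if (params$taper == "hanning") {
    0.5 * (1 - cos(2 * pi * (0:(nw - 1)) / (nw - 1)))
  } else {
    rep(1, nw)
  }
  U <- sum(w^2)

  nf <- nw %/% 2 + 1L
  Sxx <- Syy <- numeric(nf)
  Sxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + nw - 1L)]
    ys <- y[s:(s + nw - 1L)]
    if (params$detrend == "mean") {
      xs <- xs - mean(xs)
      ys <- ys - mean(ys)
    }
    X <- fft(xs * w)[seq_len(nf)]
    Y <- fft(ys * w)[seq_len(nf)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Conj(X) * Y
  }
  norm <- K * U * fs
  Sxx <- Sxx / norm
  Syy <- Syy / norm
  Sxy <- Sxy / norm
  # one-sided scaling (DC and Nyquist unique)
  two <- rep(2, nf)
  two[1] <- 1
  if (nw %% 2 == 0) two[nf] <- 1
  Sxx <- Sxx * two
  Syy <- Syy * two
  Sxy <- Sxy * two

  H <- ifelse(Sxx > 0, Sxy / Sxx, NA_complex_)
  coh <- ifelse(Sxx > 0 & Syy > 0, Mod(Sxy)^2 / (Sxx * Syy), NA_real_)
  coh <- pmin(coh, 1)

  out <- tibble(
    freq_hz = (seq_len(nf) - 1L) * fs / nw,
    psd_input = Sxx,
    psd_output = Syy,
    cross_re = Re(Sxy),
    cross_im = Im(Sxy),
    coherence = coh,
    gain = Mod(H),
    phase_deg = wrap_deg(-Arg(H) * 180 / pi)
  )
  attr(out, "fs") <- fs
  attr(out, "n_windows") <- K
  attr(out, "mean_input") <- mean(x)
  attr(out, "mean_output") <- mean(y)
  attr(out, "params") <- params
  class(out) <- c("tfa_spectra", class(out))
  out
}

#' Band-average transfer function spectra
#'
#' Averages gain, coherence and power spectral densities over the frequency
#' bins of each band (half-open `[f_lo, f_hi)`); phase is averaged
#' circularly with weights proportional to cross-spectral magnitude, which
#' suppresses noise-dominated bins. Normalized gain (% output change per %
#' input change) is computed as `gain * mean_input / output_scale` when an
#' output scale is supplied.
#'
#' @param spectra A `tfa_spectra` tibble from [compute_tfa()].
#' @param bands Band table, see [tfa_bands()].
#' @param mean_input Mean input level (mmHg); defaults to the value stored
#'   by [compute_tfa()].
#' @param output_scale Reference OxyHb scale (µM·mm) for normalized gain;
#'   `NA` if not supplied (OxyHb change signals have near-zero means, so a
#'   percent-of-mean scale must be chosen explicitly by the caller).
#' @return A tibble of class `tfa_result`: `band`, `f_lo`, `f_hi`,
#'   `n_bins`, `psd_input`, `psd_output`, `coherence`, `gain`,
#'   `normalized_gain`, `phase_deg`, `mean_input`, `mean_output`.
#' @export
band_average <- function(spectra, bands = tfa_bands(),
                         mean_input = NULL, output_scale = NULL) {
  fs <- attr(spectra, "fs")
  if (is.null(mean_input)) mean_input <- attr(spectra, "mean_input")
  mean_output <- attr(spectra, "mean_output") %||% NA_real_
  rows <- purrr::pmap(bands, function(band, f_lo, f_hi) {
    if (!is.null(fs) && f_lo >= fs / 2) {
      abort(paste0("Band ", band, " lies outside the Nyquist range."))
    }
    sel <- spectra$freq_hz >= f_lo & spectra$freq_hz < f_hi
    if (!any(sel)) abort(paste0("Band ", band, " contains no frequency bins."))
    s <- spectra[sel, ]
    wgt <- sqrt(s$cross_re^2 + s$cross_im^2)
    if (sum(wgt) == 0) wgt <- rep(1, nrow(s))
    g <- mean(s$gain)
    tibble(
      band = band, f_lo = f_lo, f_hi = f_hi, n_bins = sum(sel),
      psd_input = mean(s$psd_input), psd_output = mean(s$psd_output),
      coherence = mean(s$coherence),
      gain = g,
      normalized_gain = if (is.null(output_scale)) NA_real_ else
        normalized_gain(g, mean_input, output_scale),
      phase_deg = wrap_deg(circ_mean_deg(s$phase_deg, wgt)),
      mean_input = mean_input %||% NA_real_,
      mean_output = mean_output
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tfa_result", class(out))
  out
}

#' Normalized gain
#'
#' Converts an absolute gain (µM·mm per mmHg) to percent output change per
#' percent input change: `gain * mean_input / output_scale`. The output
#' scale is the caller's reference OxyHb magnitude; it cannot default to
#' the output mean because OxyHb concentration *changes* fluctuate around
#' zero.
#'
#' @param gain Gain, output unit per input unit.
#' @param mean_input Mean input level (e.g. mean ABP in mmHg).
#' @param output_scale Reference output magnitude (> 0).
#' @return Normalized gain, %/%.
#' @export
normalized_gain <- function(gain, mean_input, output_scale) {
  if (any(output_scale <= 0)) abort("`output_scale` must be positive.")
  gain * mean_input / output_scale
}

phase_wrap_correct_vec <- function(phases, tol_deg = 30, min_consistent = 2) {
  n <- length(phases)
  if (n < 2) abort("At least 2 channels are required for wrap correction.")
  qualify <- logical(n)
  target <- numeric(n)
  for (i in seq_len(n)) {
    others <- phases[-i]
    if (length(others) < min_consistent) next
    om <- circ_mean_deg(others)
    consistent <- all(circ_dist_deg(others, om) <= tol_deg)
    deviant <- abs(circ_dist_deg(phases[i], om) - 180) <= tol_deg
    if (consistent && deviant) {
      qualify[i] <- TRUE
      target[i] <- om
    }
  }
  if (sum(qualify) == 1) {
    i <- which(qualify)
    corrected <- phases
    corrected[i] <- wrap_deg(phases[i] + 180)
    list(phases = corrected, flag = qualify, applied = TRUE)
  } else {
    list(phases = phases, flag = rep(FALSE, n), applied = FALSE)
  }
}

#' 180-degree single-channel phase consistency correction
#'
#' Low signal amplitudes occasionally flip a single channel's band phase by
#' an accurate 180 degrees relative to the other channels of the same
#' hemisphere. When exactly one channel differs from the circular mean of
#' the remaining channels by 180 ± `tol_deg` degrees while those remaining
#' (at least `min_consistent`) agree within `tol_deg` of their own circular
#' mean, the deviant channel is shifted by 180 degrees toward the group and
#' flagged. In every other configuration (all consistent, or two or more
#' deviants) the phases are returned unchanged with a no-correction flag.
#'
#' @param data Data frame with a phase column (one row per channel), or a
#'   bare numeric vector of phases in degrees.
#' @param phase Name of the phase column.
#' @param tol_deg Consistency tolerance, degrees.
#' @param min_consistent Minimum number of agreeing remaining channels.
#' @return The input as a tibble with `phase_deg` corrected and a logical
#'   `wrap_corrected` column; attribute `correction_applied` is `TRUE` when
#'   a correction was made.
#' @examples
#' correct_phase_wrap(c(40, 41, 39, -140))
#' @export
correct_phase_wrap <- function(data, phase = "phase_deg", tol_deg = 30,
                               min_consistent = 2) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- tibble(channel = seq_along(data), phase_deg = data)
    phase <- "phase_deg"
  }
  res <- phase_wrap_correct_vec(data[[phase]], tol_deg, min_consistent)
  out <- as_tibble(data)
  out[[phase]] <- res$phases
  out$wrap_corrected <- res$flag
  attr(out, "correction_applied") <- res$applied
  out
}
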