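#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_errorbar facet_wrap facet_grid labs theme_minimal geom_rect
#'   scale_x_continuous
NULL

#' @export
ggplot2::autoplot

#' Plot the signals of a recording
#'
#' Overview facet plot of the ABP waveform, a representative NIRS channel
#' per hemisphere, and the vitals, with event markers as vertical lines.
#'
#' @param object A `nirs_recording`.
#' @param channels Channels to show (default: first long channel per
#'   hemisphere).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nirs_recording
#' @export
autoplot.nirs_recording <- function(object, channels = NULL, ...) {
  if (is.null(channels)) {
    channels <- object$channels |>
      dplyr::filter(.data$role == "long") |>
      dplyr::distinct(.data$hemisphere, .keep_all = TRUE) |>
      dplyr::pull("channel")
  }
  abp <- object$abp |>
    dplyr::transmute(time_s = .data$time_s, value = .data$abp_mmhg,
                     signal = "ABP (mmHg)")
  nir <- object$nirs |>
    dplyr::select("time_s", dplyr::all_of(channels)) |>
    tidyr::pivot_longer(-"time_s", names_to = "signal") |>
    dplyr::mutate(signal = paste0(.data$signal, " (µM·mm)"))
  df <- dplyr::bind_rows(abp, nir)
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.2) +
    ggplot2::geom_vline(data = object$events,
                        aes(xintercept = .data$time_s),
                        linetype = "dashed", colour = "red") +
    facet_wrap(~signal, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Plot transfer function spectra
#'
#' Gain, phase and coherence against frequency, with the VLF/LF/HF band
#' edges marked.
#'
#' @param object A `tfa_spectra` tibble from [compute_tfa()].
#' @param max_freq_hz Upper frequency limit of the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfa_spectra
#' @export
autoplot.tfa_spectra <- function(object, max_freq_hz = 0.5, ...) {
  df <- object |>
    dplyr::filter(.data$freq_hz > 0, .data$freq_hz <= max_freq_hz) |>
    dplyr::select("freq_hz", "gain", "phase_deg", "coherence") |>
    tidyr::pivot_longer(-"freq_hz", names_to = "quantity")
  ggplot(df, aes(x = .data$freq_hz, y = .data$value)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = c(0.02, 0.07, 0.2, 0.5),
                        linetype = "dotted") +
    facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    labs(x = "frequency (Hz)", y = NULL) +
    theme_minimal()
}

#' Coefficient plot of a phase-shift mixed model
#'
#' Fixed-effect estimates with their confidence intervals.
#'
#' @param object A `phase_lmm` object.
#' @param ... Passed to [tidy.phase_lmm()].
#' @return A ggplot object.
#' @method autoplot phase_lmm
#' @export
autoplot.phase_lmm <- function(object, ...) {
  td <- tidy(object, ...)
  ggplot(td, aes(x = .data$estimate, y = .data$term)) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$conf_low, xmax = .data$conf_high),
                  width = 0.2) +
    geom_hline(yintercept = 0, linetype = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "estimate (deg)", y = NULL) +
    theme_minimal()
}

#' Timeline of selected steady-state segments
#'
#' Shows the selected PRE/POST/2H windows against the event markers.
#'
#' @param recording A `nirs_recording`.
#' @param segments Tibble from [select_segments()].
#' @return A ggplot object.
#' @export
plot_segments <- function(recording, segments) {
  ggplot() +
    geom_rect(data = segments,
              aes(xmin = .data$start_s, xmax = .data$end_s,
                  ymin = 0, ymax = 1, fill = .data$label),
              alpha = 0.5) +
    ggplot2::geom_vline(data = recording$events,
                        aes(xintercept = .data$time_s),
                        linetype = "dashed") +
    ggplot2::geom_text(data = recording$events,
                       aes(x = .data$time_s, y = 1.05, label = .data$event),
                       angle = 90, hjust = 0, size = 3) +
    scale_x_continuous(limits = c(0, max(recording$abp$time_s))) +
    labs(x = "time (s)", y = NULL, fill = "segment") +
    theme_minimal()
}
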