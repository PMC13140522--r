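#' Run the full autoregulation analysis pipeline on one recording
#'
#' Chains every stage on a (real or synthetic) recording whose NIRS
#' channels are already in OxyHb units: artifact flagging and linear
#' interpolation on the raw ABP and NIRS signals, steady-state segment
#' selection, per-segment beat detection on ABP, beat-to-beat averaging of
#' ABP and every channel on the single ABP-derived beat grid, 10 Hz
#' resampling, Welch transfer function analysis per channel, band
#' averaging, and the 180-degree single-channel phase consistency
#' correction applied across the long channels of each hemisphere within
#' each segment and band.
#'
#' @param recording A `nirs_recording`.
#' @param criteria A [segment_criteria()].
#' @param params A [tfa_params()].
#' @param labels Segment labels to analyse.
#' @param output_scale Reference OxyHb magnitude (µM·mm) for normalized
#'   gain; `NULL` leaves normalized gain `NA`.
#' @param target_fs Uniform resampling rate, Hz.
#' @param wrap_tol_deg Tolerance of the 180-degree correction.
#' @param masks `"auto"` (default) to detect artifacts, `NULL` to skip, or
#'   a named list of masks (e.g. the generator's ground truth).
#' @return A tibble with one row per segment x channel x band:
#'   segment metadata, channel metadata, and all band-averaged TFA fields
#'   (`psd_input`, `psd_output`, `coherence`, `gain`, `normalized_gain`,
#'   `phase_deg`, `mean_input`, `mean_output`, `wrap_corrected`).
#' @examples
#' rec <- synthesize_recording(synth_config(duration_s = 1800, seed = 11))
#' res <- run_pipeline(rec, labels = "POST")
#' dplyr::filter(res, band == "LF", role == "long")
#' @export
run_pipeline <- function(recording, criteria = segment_criteria(),
                         params = tfa_params(),
                         labels = c("PRE", "POST", "2H"),
                         output_scale = 100, target_fs = 10,
                         wrap_tol_deg = 30, masks = "auto") {
  if (identical(masks, "auto")) masks <- recording_masks(recording)

  segs <- select_segments(recording, criteria, labels, masks)
  if (nrow(segs) == 0) {
    return(tibble(segment = character(), channel = character(),
                  band = character(), phase_deg = numeric()))
  }

  fs <- recording$fs_raw
  abp <- recording$abp$abp_mmhg
  if (!is.null(masks)) {
    abp <- interpolate_artifacts(abp, mask = masks$abp)
  }
  chans <- recording$channels
  nirs <- purrr::map(setNames(chans$channel, chans$channel), function(ch) {
    x <- recording$nirs[[ch]]
    if (!is.null(masks)) x <- interpolate_artifacts(x, mask = masks[[ch]])
    x
  })

  rows <- purrr::map(seq_len(nrow(segs)), function(si) {
    s <- segs$start_s[si]
    e <- segs$end_s[si]
    i0 <- floor(s * fs) + 1L
    i1 <- min(length(abp), round(e * fs) + 1L)
    abp_w <- abp[i0:i1]
    beats <- detect_beats(abp_w, fs = fs)
    abp10 <- beat_average_resample(abp_w, beats, fs = fs,
                                   target_fs = target_fs)
    mean_abp <- mean(abp_w)

    purrr::map(seq_len(nrow(chans)), function(ci) {
      ch <- chans$channel[ci]
      ch10 <- beat_average_resample(nirs[[ch]][i0:i1], beats, fs = fs,
                                    target_fs = target_fs)
      sp <- compute_tfa(abp10$value, ch10$value, fs = target_fs,
                        params = params)
      ba <- band_average(sp, params$bands, mean_input = mean_abp,
                         output_scale = output_scale)
      dplyr::bind_cols(
        tibble(segment = segs$label[si], start_s = s, end_s = e,
               channel = ch, hemisphere = chans$hemisphere[ci],
               role = chans$role[ci], separation_mm = chans$separation_mm[ci]),
        ba
      )
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()

  # 180-degree consistency correction across long channels per
  # hemisphere x segment x band
  rows$wrap_corrected <- FALSE
  key <- interaction(rows$segment, rows$hemisphere, rows$band, drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g & rows$role == "long")
    if (length(idx) >= 2) {
      res <- phase_wrap_correct_vec(rows$phase_deg[idx],
                                    tol_deg = wrap_tol_deg)
      rows$phase_deg[idx] <- res$phases
      rows$wrap_corrected[idx] <- res$flag
    }
  }
  rows
}
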