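#' Steady-state segment selection criteria
#'
#' Rules a 5-minute analysis window must satisfy: no overlap with the 5 min
#' following anaesthesia induction or the 2 min following a drug-change
#' event, at most `vital_variation_fraction` (default 10%) relative
#' variation of every monitored vital within the window, and an artifact
#' density below `max_artifact_fraction` on every signal.
#'
#' @param duration_s Window length, seconds (default 300).
#' @param ga_induction_exclusion_s Exclusion zone length after general
#'   anaesthesia induction, seconds.
#' @param drug_change_exclusion_s Exclusion zone after substantial changes
#'   of anaesthetics, opioids or vasopressors, seconds.
#' @param vital_variation_fraction Maximum allowed (max - min) / window-mean
#'   per monitored vital.
#' @param max_artifact_fraction Maximum flagged-sample fraction per signal.
#' @param vitals Vitals columns subject to the variation rule.
#' @param stride_s Candidate-window stride for [select_segments()].
#' @return A list of class `segment_criteria`.
#' @export
segment_criteria <- function(duration_s = 300,
                             ga_induction_exclusion_s = 300,
                             drug_change_exclusion_s = 120,
                             vital_variation_fraction = 0.10,
                             max_artifact_fraction = 0.05,
                             vitals = c("hr_bpm", "map_mmhg", "spo2_pct",
                                        "etco2_kpa"),
                             stride_s = 1) {
  stopifnot(duration_s > 0, ga_induction_exclusion_s > 0,
            drug_change_exclusion_s > 0,
            vital_variation_fraction > 0, vital_variation_fraction < 1)
  structure(
    list(duration_s = duration_s,
         ga_induction_exclusion_s = ga_induction_exclusion_s,
         drug_change_exclusion_s = drug_change_exclusion_s,
         vital_variation_fraction = vital_variation_fraction,
         max_artifact_fraction = max_artifact_fraction,
         vitals = vitals, stride_s = stride_s),
    class = "segment_criteria"
  )
}

# exclusion zones [start, end) derived from event markers
exclusion_zones <- function(events, criteria) {
  zones <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events$event[i]
    if (ev == "ga_induction") {
      zones[[length(zones) + 1]] <-
        c(events$time_s[i], events$time_s[i] + criteria$ga_induction_exclusion_s)
    } else if (startsWith(ev, "drug_change")) {
      zones[[length(zones) + 1]] <-
        c(events$time_s[i], events$time_s[i] + criteria$drug_change_exclusion_s)
    }
  }
  zones
}

#' Test whether a window satisfies the steady-state rules
#'
#' @param recording A `nirs_recording` (only its `vitals` and `events` are
#'   used, plus `masks` for artifact density).
#' @param start_s,end_s Window bounds, seconds.
#' @param criteria A [segment_criteria()].
#' @param masks Optional named list of logical artifact masks, one per
#'   signal, aligned with the raw sampling grid (e.g. from
#'   [flag_artifacts()] or the generator's ground truth). `NULL` means no
#'   artifact contribution.
#' @return A one-row tibble: `steady`, per-vital relative variation columns
#'   (`qc_<vital>`), `artifact_density`, `in_exclusion`, and
#'   `offending_vital` (`NA` when none).
#' @export
window_is_steady <- function(recording, start_s, end_s,
                             criteria = segment_criteria(), masks = NULL) {
  vit <- recording$vitals
  sel <- vit$time_s >= start_s & vit$time_s <= end_s
  expected <- (end_s - start_s) * recording$vitals_fs + 1
  if (sum(sel) < 0.9 * expected) {
    abort("Vitals are missing for more than 10% of the window.")
  }
  win <- vit[sel, ]

  qc <- purrr::map_dbl(setNames(criteria$vitals, criteria$vitals), function(v) {
    x <- win[[v]]
    (max(x) - min(x)) / abs(mean(x))
  })
  offending <- names(qc)[qc > criteria$vital_variation_fraction]

  dens <- 0
  if (!is.null(masks) && length(masks)) {
    fs <- recording$fs_raw
    i0 <- max(1L, floor(start_s * fs) + 1L)
    i1 <- ceiling(end_s * fs) + 1L
    dens <- max(vapply(masks, function(m) {
      mean(m[i0:min(i1, length(m))])
    }, numeric(1)))
  }

  zones <- exclusion_zones(recording$events, criteria)
  in_excl <- any(vapply(zones, function(z) start_s < z[2] && end_s > z[1],
                        logical(1)))

  out <- tibble(
    steady = length(offending) == 0 &&
      dens <= criteria$max_artifact_fraction && !in_excl,
    artifact_density = dens,
    in_exclusion = in_excl,
    offending_vital = if (length(offending)) offending[1] else NA_character_
  )
  for (v in names(qc)) out[[paste0("qc_", sub("_[a-z]+$", "", v))]] <- qc[[v]]
  out
}

# eligibility interval per label from the event markers
label_interval <- function(recording, label) {
  ev <- setNames(recording$events$time_s, recording$events$event)
  dur <- max(recording$abp$time_s)
  need <- function(nm) {
    if (!nm %in% names(ev)) {
      abort(paste0("Event marker `", nm, "` required for segment ", label, "."))
    }
    unname(ev[[nm]])
  }
  recan <- if ("recanalization" %in% names(ev)) unname(ev[["recanalization"]]) else NULL
  int <- switch(
    label,
    PRE = c(need("ga_induction"),
            if ("recan_start" %in% names(ev)) unname(ev[["recan_start"]]) else need("recanalization")),
    POST = c(need("recanalization"), need("ga_termination")),
    `2H` = c(need("ga_termination"),
             min(need("recanalization") + 7200, dur)),
    abort(paste0("Unknown segment label: ", label))
  )
  if (int[2] < int[1]) abort("Inconsistent event ordering for segment eligibility.")
  int
}

#' Select steady-state analysis segments
#'
#' Scans candidate 5-minute windows at `stride_s` resolution within each
#' label's eligibility interval (PRE: anaesthesia induction to first
#' recanalization attempt; POST: final reperfusion status to anaesthesia
#' termination; 2H: anaesthesia termination to 2 h after recanalization) and
#' returns, per label, the earliest admissible window (PRE, POST) or the
#' latest one (2H, "as late as possible"). Labels without any admissible
#' window are omitted.
#'
#' @param recording A `nirs_recording`.
#' @param criteria A [segment_criteria()].
#' @param labels Labels to search for.
#' @param masks As in [window_is_steady()]; pass `"auto"` to compute
#'   artifact masks from the raw ABP and NIRS signals with
#'   [flag_artifacts()] defaults.
#' @return A tibble with one row per found segment: `label`, `start_s`,
#'   `end_s`, and the qc columns of [window_is_steady()].
#' @export
select_segments <- function(recording, criteria = segment_criteria(),
                            labels = c("PRE", "POST", "2H"), masks = NULL) {
  if (identical(masks, "auto")) masks <- recording_masks(recording)
  dur <- criteria$duration_s
  out <- list()
  for (lab in labels) {
    int <- label_interval(recording, lab)
    if (int[2] - int[1] < dur) next
    starts <- seq(int[1], int[2] - dur, by = criteria$stride_s)
    if (lab == "2H") starts <- rev(starts)
    for (s in starts) {
      qc <- window_is_steady(recording, s, s + dur, criteria, masks)
      if (qc$steady) {
        out[[length(out) + 1]] <- dplyr::bind_cols(
          tibble(label = lab, start_s = s, end_s = s + dur), qc
        )
        break
      }
    }
  }
  if (!length(out)) {
    return(tibble(label = character(), start_s = numeric(),
                  end_s = numeric(), steady = logical()))
  }
  dplyr::bind_rows(out)
}

#' Artifact masks for every signal of a recording
#'
#' Runs [flag_artifacts()] on the ABP waveform and each NIRS channel and
#' returns the logical masks as a named list (the shape expected by
#' [window_is_steady()] and [select_segments()]).
#'
#' @param recording A `nirs_recording`.
#' @param ... Passed to [flag_artifacts()].
#' @return Named list of logical vectors.
#' @export
recording_masks <- function(recording, ...) {
  masks <- list(
    abp = flag_artifacts(recording$abp, value = "abp_mmhg",
                         fs = recording$fs_raw, ...)$is_artifact
  )
  for (ch in recording$channels$channel) {
    masks[[ch]] <- flag_artifacts(recording$nirs, value = ch,
                                  fs = recording$fs_raw, ...)$is_artifact
  }
  masks
}
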