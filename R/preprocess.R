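#' Flag artifact samples in a sampled signal
#'
#' Deterministic artifact detector combining two robust rules. A
#' running-median baseline (window `baseline_s`) is subtracted and samples
#' whose robust z-score (residual over a 95%-quantile-consistent robust
#' scale) exceeds `z_threshold` are flagged. In addition, sharp edges —
#' first differences exceeding `z_threshold` on the robust scale of the
#' differenced signal — are paired, and the span between two consecutive
#' opposite-signed edges closer than `max_gap_s` is flagged, which captures
#' square (step-and-return) artifacts and isolated spikes exactly.
#' Contiguous flagged runs longer than `max_gap_s` are marked unsalvageable
#' (too long to bridge by linear interpolation).
#'
#' @param data Data frame with a time column and a value column, or a bare
#'   numeric vector.
#' @param value Name of the value column.
#' @param fs Sampling rate in Hz; inferred from the time column if `NULL`.
#' @param z_threshold Robust z-score threshold (default 5).
#' @param max_gap_s Longest artifact run considered salvageable, seconds.
#' @param baseline_s Running-median window length, seconds.
#' @param time Name of the time column.
#' @return The input as a tibble with logical columns `is_artifact` and
#'   `unsalvageable` added (for vector input, a tibble with `value` too).
#' @export
flag_artifacts <- function(data, value = "value", fs = NULL,
                           z_threshold = 5, max_gap_s = 5,
                           baseline_s = 5, time = "time_s") {
  if (is.numeric(data) && is.null(dim(data))) {
    if (is.null(fs)) abort("`fs` is required for vector input.")
    data <- tibble(time_s = (seq_along(data) - 1) / fs, value = data)
    value <- "value"
    time <- "time_s"
  }
  x <- data[[value]]
  if (is.null(fs)) fs <- 1 / median(diff(data[[time]]))
  n <- length(x)

  w <- round(baseline_s * fs)
  w <- max(3L, if (w %% 2 == 0) w + 1L else w)
  base <- if (n > w) stats::runmed(x, w, endrule = "median") else rep(median(x), n)
  resid <- x - base
  # 95%-quantile-based robust scale: tolerant of narrowband residual shape,
  # still immune to a small artifact fraction
  dev <- abs(resid - median(resid))
  scale_v <- quantile(dev, 0.95) / 1.6449
  if (scale_v <= 0) scale_v <- .Machine$double.eps * max(1, max(abs(x)))
  zv <- abs(resid) / scale_v

  # sharp edges on the differenced signal; square artifacts are bridged
  # between an up-edge and the matching down-edge
  d <- diff(x)
  scale_d <- 1.4826 * median(abs(d - median(d)))
  if (scale_d <= 0) scale_d <- .Machine$double.eps * max(1, max(abs(x)))
  zd <- abs(d) / scale_d
  edges <- which(zd > z_threshold)
  bridged <- rep(FALSE, n)
  if (length(edges) >= 2) {
    for (j in seq_len(length(edges) - 1L)) {
      e1 <- edges[j]
      e2 <- edges[j + 1L]
      if ((e2 - e1) / fs <= max_gap_s && d[e1] * d[e2] < 0) {
        bridged[(e1 + 1L):e2] <- TRUE
      }
    }
  }

  mask <- zv > z_threshold | bridged
  if (all(mask)) abort("Every sample is flagged as artifact; nothing to keep.")

  r <- rle(mask)
  too_long <- r$values & (r$lengths / fs > max_gap_s)
  unsalv <- inverse.rle(list(values = too_long, lengths = r$lengths))

  out <- as_tibble(data)
  out$is_artifact <- mask
  out$unsalvageable <- unsalv
  out
}

#' Replace flagged samples by linear interpolation
#'
#' Flagged samples are replaced by linear interpolation between the nearest
#' unflagged neighbours; flagged runs at the series edges are filled with
#' the nearest unflagged value. All other samples are returned bit-identical.
#'
#' @param data Data frame containing the value column and a logical mask
#'   column (e.g. output of [flag_artifacts()]), or a numeric vector.
#' @param value Name of the value column.
#' @param mask Name of the logical mask column, or a logical vector.
#' @return The input tibble with the value column repaired (for vector
#'   input, a numeric vector).
#' @examples
#' interpolate_artifacts(c(1, 9, 3), mask = c(FALSE, TRUE, FALSE))
#' @export
interpolate_artifacts <- function(data, value = "value", mask = "is_artifact") {
  vec_in <- is.numeric(data) && is.null(dim(data))
  x <- if (vec_in) data else data[[value]]
  m <- if (is.logical(mask)) mask else data[[mask]]
  if (length(m) != length(x)) abort("Mask length must match the series.")
  if (all(m)) abort("Mask flags every sample; interpolation impossible.")
  if (any(m)) {
    keep <- which(!m)
    x[m] <- approx(keep, x[keep], xout = which(m), rule = 2)$y
  }
  if (vec_in) return(x)
  out <- as_tibble(data)
  out[[value]] <- x
  out
}

#' Detect beats on an arterial blood pressure waveform
#'
#' Derivative-based systolic upstroke detection: beat onsets are placed at
#' local maxima of the first derivative (maximum-upstroke points), accepted
#' greedily in order of decreasing slope subject to a refractory period, so
#' secondary upstrokes within a beat are discarded.
#'
#' @param data Data frame with time and ABP columns, or a numeric vector.
#' @param value Name of the ABP column.
#' @param fs Sampling rate, Hz (>= 50); inferred from time if `NULL`.
#' @param refractory_s Minimum inter-beat interval, seconds.
#' @param time Name of the time column.
#' @return A tibble with columns `beat` and `onset_s`.
#' @export
detect_beats <- function(data, value = "abp_mmhg", fs = NULL,
                         refractory_s = 0.3, time = "time_s") {
  if (is.numeric(data) && is.null(dim(data))) {
    if (is.null(fs)) abort("`fs` is required for vector input.")
    t0 <- 0
    x <- data
  } else {
    x <- data[[value]]
    tt <- data[[time]]
    if (is.null(fs)) fs <- 1 / median(diff(tt))
    t0 <- tt[1]
  }
  if (fs < 50) abort("`fs` must be at least 50 Hz for beat detection.")
  n <- length(x)
  if (n / fs < 10) abort("At least 10 s of signal are required.")
  if (sd(x) < 1e-9) abort("No beats detected: flat signal.")

  d <- diff(x) * fs
  loc <- which(d > c(-Inf, d[-length(d)]) & d >= c(d[-1], -Inf) & d > 0)
  if (!length(loc)) abort("No beats detected: no rising edges.")
  thr <- 0.4 * quantile(d[loc], 0.95)
  loc <- loc[d[loc] > thr]
  if (length(loc) < 2) abort("No beats detected: aperiodic input.")

  ord <- loc[order(d[loc], decreasing = TRUE)]
  accepted <- numeric(0)
  ref_n <- refractory_s * fs
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= ref_n)) {
      accepted <- c(accepted, i)
    }
  }
  on <- sort(accepted)
  if (length(on) < 2) abort("No beats detected: fewer than 2 beats.")
  # d[i] spans samples i..i+1; the upstroke maximum sits at the midpoint
  tibble(beat = seq_along(on), onset_s = t0 + (on - 0.5) / fs)
}

#' Beat-to-beat average and resample to a uniform grid
#'
#' Computes the mean of the signal over each inter-onset interval, places
#' each mean at the interval midpoint, and linearly interpolates onto a
#' uniform grid at `target_fs` spanning the first to the last beat onset
#' (edge values extended by the nearest beat mean).
#'
#' @param data Data frame with time and value columns, or a numeric vector
#'   sampled at `fs` from time 0.
#' @param beats Beat table from [detect_beats()] (columns `beat`, `onset_s`).
#' @param value,time Column names.
#' @param fs Sampling rate of `data` (vector input only).
#' @param target_fs Output sampling rate, Hz (default 10).
#' @return A tibble `time_s`, `value` with attributes `fs = target_fs` and
#'   `beat_means` (the intermediate beat-mean series).
#' @export
beat_average_resample <- function(data, beats, value = "value",
                                  time = "time_s", fs = NULL,
                                  target_fs = 10) {
  if (is.numeric(data) && is.null(dim(data))) {
    if (is.null(fs)) abort("`fs` is required for vector input.")
    data <- tibble(time_s = (seq_along(data) - 1) / fs, value = data)
    value <- "value"
    time <- "time_s"
  }
  on <- beats$onset_s
  if (length(on) < 2) abort("At least 2 beats are required.")
  tt <- data[[time]]
  x <- data[[value]]
  idx <- findInterval(tt, on)
  inb <- idx >= 1 & idx < length(on)
  means <- tapply(x[inb], idx[inb], mean)
  mid <- (on[-length(on)] + on[-1]) / 2
  mid <- mid[as.integer(names(means))]

  grid <- on[1] + seq(0, floor((on[length(on)] - on[1]) * target_fs)) / target_fs
  y <- approx(mid, as.numeric(means), xout = grid, rule = 2)$y
  out <- tibble(time_s = grid, value = y)
  attr(out, "fs") <- target_fs
  attr(out, "beat_means") <- tibble(mid_s = mid, mean = as.numeric(means))
  out
}
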