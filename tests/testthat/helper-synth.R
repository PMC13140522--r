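# compact configurations used across tests

# short recording with a single analysable (POST-like) interval
short_config <- function(seed = 1, duration_s = 400, ...) {
  synth_config(
    duration_s = duration_s, seed = seed,
    event_times = c(ga_induction = 10, recanalization = 20,
                    ga_termination = duration_s - 20),
    ...
  )
}

# noiseless pure-linear configuration: no scalp mixing, identical transfer
# in every band, so the imposed (gain, phase) is the exact ground truth
linear_config <- function(gain, phase_deg, seed = 1, duration_s = 700) {
  synth_config(
    duration_s = duration_s, seed = seed,
    extracerebral_fraction = 0, short_extracerebral_fraction = 0,
    band_transfer = default_band_transfer(
      lf_gain = gain, lf_phase_deg = phase_deg,
      vlf_gain = gain, vlf_phase_deg = phase_deg,
      hf_gain = gain, hf_phase_deg = phase_deg
    ),
    event_times = c(ga_induction = 10, recanalization = 20,
                    ga_termination = duration_s - 20)
  )
}

# forward-model every NIRS channel to two-wavelength optical density and
# convert back, exercising the Beer-Lambert stage inside pipeline tests
pipe_through_mbll <- function(rec) {
  for (ch in rec$channels$channel) {
    hb <- tibble::tibble(time_s = rec$nirs$time_s,
                         oxyhb = rec$nirs[[ch]],
                         deoxyhb = -0.3 * rec$nirs[[ch]])
    od <- forward_mbll(hb)
    rec$nirs[[ch]] <- mbll_convert(od)$oxyhb
  }
  rec
}

# independent brute-force steady-segment search at 1 s stride
brute_force_segments <- function(rec, criteria, labels, masks = NULL) {
  out <- list()
  for (lab in labels) {
    int <- tryCatch(nirstfa:::label_interval(rec, lab),
                    error = function(e) NULL)
    if (is.null(int) || int[2] - int[1] < criteria$duration_s) next
    starts <- seq(int[1], int[2] - criteria$duration_s, by = 1)
    ok <- starts[vapply(starts, function(s) {
      window_is_steady(rec, s, s + criteria$duration_s, criteria,
                       masks)$steady
    }, logical(1))]
    if (!length(ok)) next
    out[[lab]] <- if (lab == "2H") max(ok) else min(ok)
  }
  out
}
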