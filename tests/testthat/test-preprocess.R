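test_that("clean synthetic signals yield an empty artifact mask", {
  rec <- synthesize_recording(short_config(seed = 42))
  fl <- flag_artifacts(rec$abp, value = "abp_mmhg", fs = rec$fs_raw)
  expect_equal(sum(fl$is_artifact), 0)
})

test_that("injected square artifacts are detected against ground truth", {
  for (seed in 1:3) {
    rec <- synthesize_recording(short_config(
      seed = seed, duration_s = 600,
      artifact_spec = list(count = 3, amplitude = 60, duration_s = 2)
    ))
    for (sig in c("abp", "IH_L1", "CH_S1")) {
      x <- if (sig == "abp") rec$abp$abp_mmhg else rec$nirs[[sig]]
      fl <- flag_artifacts(x, fs = rec$fs_raw)
      truth <- rec$truth$artifact_mask[[sig]]
      sens <- sum(fl$is_artifact & truth) / sum(truth)
      fpr <- sum(fl$is_artifact & !truth) / sum(!truth)
      expect_gte(sens, 0.95)
      expect_lt(fpr, 0.01)
    }
  }
})

test_that("a single spike on a constant series is flagged exactly", {
  x <- rep(5, 1000)
  x[500] <- 5 + 50
  fl <- flag_artifacts(x, fs = 50)
  expect_equal(which(fl$is_artifact), 500)
})

test_that("interpolation replaces only flagged samples", {
  expect_equal(interpolate_artifacts(c(1, 9, 3),
                                     mask = c(FALSE, TRUE, FALSE)),
               c(1, 2, 3))
  x <- rnorm(200)
  expect_identical(interpolate_artifacts(x, mask = rep(FALSE, 200)), x)
  set.seed(10)
  for (rep in 1:5) {
    x <- rnorm(500)
    m <- runif(500) < 0.15
    m[c(1, 500)] <- m[c(1, 500)] & TRUE  # edges allowed
    y <- interpolate_artifacts(x, mask = m)
    expect_identical(y[!m], x[!m])
    expect_true(all(is.finite(y)))
    # idempotence under the same mask
    expect_identical(interpolate_artifacts(y, mask = m), y)
  }
  expect_error(interpolate_artifacts(x, mask = rep(TRUE, 500)), "every sample")
})

test_that("beat detection counts and locates beats", {
  cfg <- short_config(seed = 2, hr_bpm = 60)
  rec <- synthesize_recording(cfg)
  i <- rec$abp$time_s <= 300
  b <- detect_beats(rec$abp$abp_mmhg[i], fs = rec$fs_raw)
  expect_gte(nrow(b), 299)
  expect_lte(nrow(b), 301)

  expect_error(detect_beats(rep(80, 1000), fs = 50), "[Nn]o beats")
  expect_error(detect_beats(rnorm(100), fs = 50), "10 s")

  # jittered beats recovered within one raw sample of the ground truth
  recj <- synthesize_recording(short_config(seed = 9, hr_bpm = 60,
                                            hr_jitter_frac = 0.03))
  bj <- detect_beats(recj$abp, value = "abp_mmhg", fs = recj$fs_raw)
  err <- vapply(bj$onset_s,
                function(t) min(abs(recj$truth$beat_onset_s - t)),
                numeric(1))
  expect_lte(max(err) * recj$fs_raw, 1)
  expect_equal(nrow(bj), length(recj$truth$beat_onset_s))
})

test_that("beat averaging and resampling preserve level, grid and slope", {
  beats <- tibble::tibble(beat = 1:31, onset_s = 0:30)
  const <- rep(7.5, 30 * 50 + 1)
  out <- beat_average_resample(const, beats, fs = 50)
  expect_true(all(abs(out$value - 7.5) < 1e-12))
  expect_equal(nrow(out), floor(30 * 10) + 1)

  ramp <- seq(0, 60, length.out = 30 * 50 + 1)  # slope 2 per second
  outr <- beat_average_resample(ramp, beats, fs = 50)
  fit <- coef(lm(value ~ time_s, data = outr))
  expect_lt(abs(fit[["time_s"]] - 2) / 2, 0.01)

  expect_error(beat_average_resample(const, beats[1, , drop = FALSE],
                                     fs = 50), "2 beats")
})

test_that("beat-averaging a beat-synchronous pulsatile waveform is constant", {
  cfg <- short_config(seed = 6, hr_bpm = 60, lfo_amplitude_mmhg = 0,
                      resp_amplitude_mmhg = 0, abp_broadband_sd_mmhg = 0)
  rec <- synthesize_recording(cfg)
  b <- detect_beats(rec$abp, value = "abp_mmhg", fs = rec$fs_raw)
  out <- beat_average_resample(rec$abp$abp_mmhg, b, fs = rec$fs_raw)
  core <- out$value[out$time_s > 5 & out$time_s < 390]
  expect_lt((max(core) - min(core)) / abs(mean(core)), 1e-6)
})

test_that("the preprocess chain preserves a 0.1 Hz oscillation amplitude", {
  rec <- synthesize_recording(short_config(
    seed = 13, duration_s = 600, lfo_amplitude_mmhg = 2,
    abp_broadband_sd_mmhg = 0, resp_amplitude_mmhg = 0
  ))
  b <- detect_beats(rec$abp, value = "abp_mmhg", fs = rec$fs_raw)
  out <- beat_average_resample(rec$abp$abp_mmhg, b, fs = rec$fs_raw)
  x <- out$value - mean(out$value)
  t <- out$time_s
  # amplitude of the 0.1 Hz component by quadrature demodulation
  amp <- 2 * sqrt(mean(x * sin(2 * pi * 0.1 * t))^2 +
                    mean(x * cos(2 * pi * 0.1 * t))^2)
  expect_lt(abs(amp - 2) / 2, 0.05)
})
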