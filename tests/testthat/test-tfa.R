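broadband <- function(n, seed = 1) {
  set.seed(seed)
  x <- as.numeric(stats::filter(rnorm(n + 500), rep(1, 3) / 3, sides = 1))
  x[!is.na(x)][seq_len(n)]
}

test_that("the identity system gives unit gain, zero phase, unit coherence", {
  x <- broadband(3000)
  sp <- compute_tfa(x, x, fs = 10)
  expect_lt(max(abs(sp$gain - 1)), 1e-6)
  expect_lt(max(abs(sp$phase_deg)), 1e-6)
  expect_gte(min(sp$coherence), 1 - 1e-9)
})

test_that("a pure delay shows the analytic phase and gain", {
  fs <- 10
  x <- broadband(6000)
  y <- 2 * dplyr::lag(x, n = fs * 1.0, default = 0)  # 1.0 s delay, gain 2
  keep <- 201:6000
  sp <- compute_tfa(x[keep], y[keep], fs = fs)
  i <- which.min(abs(sp$freq_hz - 0.1))
  expect_lt(abs(sp$phase_deg[i] - 36), 1)       # 360 * 0.1 Hz * 1 s
  ba <- band_average(sp)
  lf <- ba[ba$band == "LF", ]
  expect_lt(abs(lf$gain - 2) / 2, 0.02)
  expect_gte(lf$coherence, 0.99)
})

test_that("independent noise shows only null-level coherence", {
  # Monte-Carlo null distribution of LF band coherence for this window count
  null_coh <- vapply(1:100, function(r) {
    set.seed(3000 + r)
    a <- rnorm(3000)
    b <- rnorm(3000)
    sp <- compute_tfa(a, b, fs = 10)
    band_average(sp)$coherence[2]
  }, numeric(1))
  crit <- quantile(null_coh, 0.95)
  probe <- vapply(1:40, function(r) {
    set.seed(9000 + r)
    sp <- compute_tfa(rnorm(3000), rnorm(3000), fs = 10)
    band_average(sp)$coherence[2]
  }, numeric(1))
  expect_gte(mean(probe < crit), 0.85)
  expect_lt(crit, 0.5)  # far below any physiological coupling level
})

test_that("single-window Welch equals the direct DFT cross-spectrum", {
  n <- 2048
  fs <- 10
  x <- broadband(n, seed = 7)
  set.seed(8)
  y <- 0.5 * x + rnorm(n)
  sp <- compute_tfa(x, y, fs = fs,
                    params = tfa_params(window_s = n / fs,
                                        overlap_fraction = 0,
                                        taper = "none", detrend = "mean"))
  xc <- x - mean(x)
  yc <- y - mean(y)
  X <- fft(xc)
  Y <- fft(yc)
  nf <- n / 2 + 1
  two <- rep(2, nf); two[c(1, nf)] <- 1
  sxx <- Mod(X[1:nf])^2 / (n * fs) * two
  sxy <- Conj(X[1:nf]) * Y[1:nf] / (n * fs) * two
  expect_lt(max(abs(sp$psd_input - sxx) / pmax(sxx, 1e-300)), 1e-10)
  got_sxy <- complex(real = sp$cross_re, imaginary = sp$cross_im)
  expect_lt(max(Mod(got_sxy - sxy) / pmax(Mod(sxy), 1e-300)), 1e-10)
})

test_that("band averaging reproduces flat and linear gain profiles", {
  sp <- tibble::tibble(
    freq_hz = seq(0, 0.5, by = 0.01),
    psd_input = 1, psd_output = 4,
    cross_re = 2, cross_im = 0,
    coherence = 1, gain = 2, phase_deg = 10
  )
  attr(sp, "fs") <- 10
  attr(sp, "mean_input") <- 100
  attr(sp, "mean_output") <- 0
  ba <- band_average(sp, mean_input = 100, output_scale = 200)
  expect_equal(ba$gain, rep(2, 3))
  expect_equal(ba$phase_deg, rep(10, 3))
  expect_equal(ba$normalized_gain, rep(1, 3))

  sp2 <- dplyr::mutate(sp, gain = 1 + freq_hz)  # linear profile
  attr(sp2, "fs") <- 10
  ba2 <- band_average(sp2, mean_input = 100)
  # bins in [0.07, 0.2): 0.07 .. 0.19 -> mean 1.13
  expect_equal(ba2$gain[ba2$band == "LF"], mean(1 + seq(0.07, 0.19, 0.01)),
               tolerance = 1e-12)

  bad <- tibble::tibble(band = "X", f_lo = 6, f_hi = 8)
  expect_error(band_average(sp, bands = bad), "Nyquist")
})

test_that("normalized gain follows its definition and rejects bad scales", {
  expect_equal(normalized_gain(10, 100, 1000), 1)
  expect_error(normalized_gain(10, 100, 0), "positive")
})

test_that("coherence stays in [0, 1] and scaling laws hold", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(2500)
    y <- 0.3 * x + rnorm(2500)
    sp <- compute_tfa(x, y, fs = 10)
    expect_true(all(sp$coherence >= 0 & sp$coherence <= 1, na.rm = TRUE))
    spk <- compute_tfa(x, 5 * y, fs = 10)
    expect_equal(spk$gain, 5 * sp$gain, tolerance = 1e-9)
    expect_equal(spk$coherence, sp$coherence, tolerance = 1e-9)
    expect_equal(spk$phase_deg, sp$phase_deg, tolerance = 1e-9)
    # phase antisymmetry under input/output swap
    rev <- compute_tfa(y, x, fs = 10)
    ok <- abs(abs(sp$phase_deg) - 180) > 1  # away from the wrap point
    expect_equal(rev$phase_deg[ok], -sp$phase_deg[ok], tolerance = 1e-6)
  }
})

test_that("validation of series and window arguments", {
  expect_error(compute_tfa(rnorm(100), rnorm(101), fs = 10), "length")
  expect_error(compute_tfa(rnorm(100), rnorm(100), fs = 10), "window")
  x <- rnorm(2000)
  x[5] <- NA
  expect_error(compute_tfa(x, rnorm(2000), fs = 10), "finite")
})

test_that("180-degree correction fixes exactly one deviant channel", {
  got <- correct_phase_wrap(c(40, 41, 39, -140))
  expect_equal(got$phase_deg, c(40, 41, 39, 40))
  expect_equal(which(got$wrap_corrected), 4)
  expect_true(attr(got, "correction_applied"))

  same <- correct_phase_wrap(c(40, 41, 39, 38))
  expect_equal(same$phase_deg, c(40, 41, 39, 38))
  expect_false(attr(same, "correction_applied"))

  two <- correct_phase_wrap(c(40, -140, 39, -141))
  expect_equal(two$phase_deg, c(40, -140, 39, -141))
  expect_false(attr(two, "correction_applied"))

  expect_error(correct_phase_wrap(40), "2 channels")

  # data-frame interface keeps other columns
  df <- tibble::tibble(channel = c("a", "b", "c"),
                       phase_deg = c(-10, -12, 170))
  out <- correct_phase_wrap(df)
  expect_equal(out$phase_deg, c(-10, -12, -10))
  expect_equal(out$channel, df$channel)
})

test_that("generator transfer functions are recovered across the phase range", {
  for (ph in c(-60, 0, 60)) {
    rec <- synthesize_recording(linear_config(gain = 10, phase_deg = ph,
                                              seed = 400 + ph))
    i <- rec$abp$time_s >= 20 & rec$abp$time_s <= 620
    sp <- compute_tfa(rec$abp$abp_mmhg[i], rec$nirs$CH_L2[i],
                      fs = rec$fs_raw)
    lf <- band_average(sp)[2, ]
    expect_lt(abs(lf$phase_deg - ph), 2)
    expect_lt(abs(lf$gain - 10) / 10, 0.03)
  }
})
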