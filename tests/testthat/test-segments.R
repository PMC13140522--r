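test_that("constant vitals with no events in range are steady", {
  rec <- synthesize_recording(synth_config(
    duration_s = 1500, seed = 1,
    event_times = c(ga_induction = 100, recanalization = 1000,
                    ga_termination = 1400)
  ))
  crit <- segment_criteria()
  qc <- window_is_steady(rec, 500, 800, crit)
  expect_true(qc$steady)
  expect_true(is.na(qc$offending_vital))
})

test_that("a MAP ramp beyond 10% of the window mean is rejected", {
  vs <- default_vitals_spec()
  vs$noise_sd[] <- 0
  vs$drift_per_s["map"] <- 15 / 300  # 80 -> 95 mmHg across any 300 s window
  rec <- synthesize_recording(synth_config(
    duration_s = 1500, seed = 2, vitals_spec = vs,
    event_times = c(ga_induction = 100, recanalization = 1000,
                    ga_termination = 1400)
  ))
  qc <- window_is_steady(rec, 500, 800, segment_criteria())
  expect_false(qc$steady)
  expect_equal(qc$offending_vital, "map_mmhg")
  expect_gt(qc$qc_map, 0.10)
})

test_that("anaesthesia-induction and drug-change exclusion boundaries hold", {
  rec <- synthesize_recording(synth_config(
    duration_s = 2000, seed = 3,
    event_times = c(ga_induction = 100, recanalization = 1200,
                    drug_change = 1250, ga_termination = 1900)
  ))
  crit <- segment_criteria()
  # 5-min zone after induction at t=100
  expect_false(window_is_steady(rec, 100 + 240, 100 + 540, crit)$steady)
  expect_false(window_is_steady(rec, 100 + 299, 100 + 599, crit)$steady)
  expect_true(window_is_steady(rec, 100 + 301, 100 + 601, crit)$steady)
  # 2-min zone after the drug change at t=1250
  expect_false(window_is_steady(rec, 1250 + 119, 1250 + 419, crit)$steady)
  expect_true(window_is_steady(rec, 1250 + 121, 1250 + 421, crit)$steady)
})

test_that("selection agrees with the brute-force 1 s scan", {
  set.seed(77)
  for (k in 1:6) {
    exc <- tibble::tibble(
      vital = sample(c("map", "hr"), 1),
      time_s = sample(250:900, 1),
      amplitude = sample(c(0, 12, 20), 1),
      duration_s = sample(60:200, 1)
    )
    vs <- modifyList(default_vitals_spec(), list(excursions = exc))
    cfg <- synth_config(
      duration_s = 1500, seed = 1000 + k,
      artifact_spec = list(count = 2, amplitude = 60, duration_s = 2),
      event_times = c(ga_induction = sample(20:80, 1), recan_start = 650,
                      recanalization = 700,
                      drug_change = sample(705:760, 1),
                      ga_termination = 1100),
      vitals_spec = vs
    )
    rec <- synthesize_recording(cfg)
    crit <- segment_criteria()
    masks <- recording_masks(rec)
    segs <- select_segments(rec, crit, masks = masks)
    bf <- brute_force_segments(rec, crit, c("PRE", "POST", "2H"), masks)
    expect_setequal(segs$label, names(bf))
    for (lab in segs$label) {
      expect_equal(segs$start_s[segs$label == lab], bf[[lab]])
    }
  }
})

test_that("a single admissible window is returned exactly", {
  # vitals unsteady everywhere except one 300 s plateau in the POST interval
  vs <- default_vitals_spec()
  vs$noise_sd[] <- 0
  exc <- tibble::tibble(
    vital = c("map", "map"),
    time_s = c(0, 1001),
    amplitude = c(30, 30),
    duration_s = c(700, 2000)
  )
  vs$excursions <- exc  # plateau only over samples 700..1000
  rec <- synthesize_recording(synth_config(
    duration_s = 1500, seed = 5, vitals_spec = vs,
    event_times = c(ga_induction = 20, recanalization = 600,
                    ga_termination = 1400)
  ))
  crit <- segment_criteria()
  segs <- select_segments(rec, crit, labels = "POST")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_s, 700)
  bf <- brute_force_segments(rec, crit, "POST")
  expect_equal(bf$POST, 700)
})

test_that("everywhere-unsteady vitals yield no segments", {
  vs <- default_vitals_spec()
  vs$noise_sd["map"] <- 8  # far beyond the 10% rule at MAP 80
  rec <- synthesize_recording(synth_config(
    duration_s = 1500, seed = 6, vitals_spec = vs,
    event_times = c(ga_induction = 20, recanalization = 600,
                    ga_termination = 1400)
  ))
  segs <- select_segments(rec, segment_criteria(), labels = "POST")
  expect_equal(nrow(segs), 0)
})

test_that("all three labels are found on an admissible recording", {
  rec <- synthesize_recording(synth_config(duration_s = 1800, seed = 7))
  segs <- select_segments(rec, segment_criteria())
  expect_setequal(segs$label, c("PRE", "POST", "2H"))
  expect_equal(nrow(segs), 3)
  expect_true(all(segs$end_s - segs$start_s == 300))
  # no selected segment overlaps any exclusion zone
  zones <- nirstfa:::exclusion_zones(rec$events, segment_criteria())
  for (i in seq_len(nrow(segs))) {
    for (z in zones) {
      expect_false(segs$start_s[i] < z[2] && segs$end_s[i] > z[1])
    }
  }
})

test_that("tightening the variation threshold never adds segments", {
  rec <- synthesize_recording(synth_config(duration_s = 1800, seed = 8))
  loose <- select_segments(rec, segment_criteria(vital_variation_fraction = 0.10))
  tight <- select_segments(rec, segment_criteria(vital_variation_fraction = 0.02))
  expect_true(all(tight$label %in% loose$label))
})
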