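test_that("an exact constant side-to-side offset degenerates gracefully", {
  tab <- synthesize_subject_table(subject_sim_spec(n_subjects = 10, seed = 1))
  tab$phase_deg[tab$hemisphere == "ischaemic"] <-
    tab$phase_deg[tab$hemisphere == "contralateral"] + 10
  res <- paired_side_test(tab)
  expect_equal(res$estimate, 10)
  expect_equal(res$p_value, 0)
  expect_match(res$method, "degenerate")
})

test_that("paired test errors without both hemispheres or enough pairs", {
  tab <- synthesize_subject_table(subject_sim_spec(n_subjects = 10, seed = 2))
  expect_error(paired_side_test(tab[tab$hemisphere == "ischaemic", ]),
               "[Bb]oth hemispheres")
  expect_error(paired_side_test(tab[tab$subject_id %in% c("S001", "S002"), ]),
               "3 complete")
})

test_that("the normality screen switches to the signed-rank test", {
  tab <- synthesize_subject_table(subject_sim_spec(n_subjects = 30, seed = 3))
  # heavy-tailed contamination of the differences
  ih <- tab$hemisphere == "ischaemic"
  set.seed(4)
  tab$phase_deg[ih] <- tab$phase_deg[ih] +
    ifelse(runif(sum(ih)) < 0.2, 300, 0)
  res <- paired_side_test(tab)
  expect_equal(res$method, "Wilcoxon signed-rank")
})

brute_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min((p * m / r)[r >= r[i]]))
  }, numeric(1))
}

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.3), 0.3)
  set.seed(5)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(fdr_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(0.5, NA)), "finite")
})

test_that("a zero-variance-subject generator reduces the LMM to OLS", {
  tab <- synthesize_subject_table(subject_sim_spec(
    n_subjects = 30, seed = 6, between_subject_sd_deg = 0,
    etco2_slope_deg_per_kpa = c(ischaemic = -20, contralateral = -5)
  ))
  fit <- fit_phase_lmm(tab, fixed = "etco2", ss_regressor = FALSE)
  ols <- lm(phase_deg ~ hemisphere + etco2 + hemisphere:etco2,
            data = fit$data)
  td <- tidy(fit)
  expect_equal(td$estimate, unname(coef(ols)[td$term]), tolerance = 1e-6)
})

test_that("estimates are invariant to row order", {
  tab <- synthesize_subject_table(subject_sim_spec(n_subjects = 25, seed = 7))
  fit1 <- fit_phase_lmm(tab, fixed = "etco2")
  set.seed(8)
  fit2 <- fit_phase_lmm(tab[sample(nrow(tab)), ], fixed = "etco2")
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate, tolerance = 1e-8)
})

test_that("one observation per subject is rejected, never a crash", {
  tab <- synthesize_subject_table(subject_sim_spec(n_subjects = 30, seed = 9))
  tab <- tab[tab$hemisphere == "ischaemic", ]
  expect_error(fit_phase_lmm(tab, ss_regressor = FALSE),
               "Mixed-model fit failed")
  # two observations per subject but no between-subject variance in the
  # generator: the fit must remain valid, with its singularity status exposed
  tab2 <- synthesize_subject_table(subject_sim_spec(
    n_subjects = 30, seed = 9, between_subject_sd_deg = 0
  ))
  fit2 <- fit_phase_lmm(tab2, ss_regressor = FALSE)
  expect_s3_class(fit2, "phase_lmm")
  expect_true(is.logical(fit2$singular))
  expect_true(is.finite(glance(fit2)$sd_subject))
})

test_that("sparse categorical levels are refused", {
  tab <- synthesize_subject_table(subject_sim_spec(n_subjects = 20, seed = 10))
  tab$rare <- ifelse(tab$subject_id == "S001", "yes", "no")
  expect_error(fit_phase_lmm(tab, fixed = "rare"), "fewer than")
  expect_error(fit_phase_lmm(tab, fixed = "nope"), "not in table")
})

test_that("model summaries expose variance components and fit indices", {
  tab <- synthesize_subject_table(subject_sim_spec(
    n_subjects = 38, seed = 11,
    etco2_slope_deg_per_kpa = c(ischaemic = -26.7, contralateral = 0)
  ))
  fit <- fit_phase_lmm(tab, fixed = "etco2")
  g <- glance(fit)
  expect_equal(g$nobs, 76)
  expect_equal(g$n_subjects, 38)
  expect_gte(g$r2_conditional, g$r2_marginal)
  expect_true(is.finite(g$aic))
  td <- tidy(fit)
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  it <- interaction_tests(fit)
  expect_true("hemisphere:etco2" %in% it$term)
  expect_true(all(it$df1 >= 1))
})

test_that("the short-separation regressor enters as a fixed effect", {
  tab <- synthesize_subject_table(subject_sim_spec(n_subjects = 20, seed = 12))
  fit <- fit_phase_lmm(tab)
  expect_true("ss_phase_deg" %in% tidy(fit)$term)
  fit0 <- fit_phase_lmm(tab, ss_regressor = FALSE)
  expect_false("ss_phase_deg" %in% tidy(fit0)$term)
})
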