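#' Specification for simulated per-subject TFA result tables
#'
#' Describes the generative model behind [synthesize_subject_table()]: one
#' low-frequency phase-shift observation per subject x hemisphere x time
#' segment, with a Gaussian subject random intercept, optional hemisphere
#' effect, optional hemisphere-specific ETCO2 slopes, optional
#' outcome-group-specific time-segment slopes, and clinically plausible
#' covariates (age, ETCO2, mean ABP, NIHSS, mRS, outcome labels). Default
#' means and spreads are anchored at a stroke-EVT cohort: LF phase near 40
#' degrees (residual SD 22), age 69.6 (13.9) years, ETCO2 4.59 (0.45) kPa,
#' mean ABP near 80 mmHg.
#'
#' @param n_subjects Number of subjects (> 0).
#' @param segments Character vector of time segments to simulate, from
#'   `c("PRE", "POST", "2H")`.
#' @param phase_mean_deg Population mean LF phase shift, degrees.
#' @param phase_sd_deg Residual (within-subject) SD of phase, degrees (> 0).
#' @param between_subject_sd_deg SD of the subject random intercept.
#' @param hemisphere_effect_deg Ischaemic-minus-contralateral fixed shift.
#' @param etco2_slope_deg_per_kpa Named vector
#'   `c(ischaemic = , contralateral = )`: phase change per kPa ETCO2
#'   (centred at its mean) in each hemisphere.
#' @param segment_slopes_deg Either `NULL` (no time trend) or a named vector
#'   `c(good = , poor = )` of degrees per segment step (PRE=0, POST=1, 2H=2)
#'   applied according to each subject's 90-day outcome group.
#' @param outcome_good_fraction Fraction of subjects assigned to the good
#'   (independent, mRS < 3) outcome group.
#' @param ss_phase_mean_deg,ss_phase_sd_deg Distribution of the
#'   short-separation-channel TFA phase regressor.
#' @param ss_effect Linear leakage of the short-separation phase into the
#'   long-channel phase (0 = none).
#' @param age_mean,age_sd,etco2_mean,etco2_sd,map_mean,map_sd Covariate
#'   distributions.
#' @param seed Integer seed.
#' @return A validated list of class `subject_sim_spec`.
#' @export
subject_sim_spec <- function(n_subjects = 38,
                             segments = "POST",
                             phase_mean_deg = 40,
                             phase_sd_deg = 22,
                             between_subject_sd_deg = 15,
                             hemisphere_effect_deg = 0,
                             etco2_slope_deg_per_kpa = c(ischaemic = 0,
                                                         contralateral = 0),
                             segment_slopes_deg = NULL,
                             outcome_good_fraction = 0.5,
                             ss_phase_mean_deg = 10,
                             ss_phase_sd_deg = 20,
                             ss_effect = 0,
                             age_mean = 69.6, age_sd = 13.9,
                             etco2_mean = 4.59, etco2_sd = 0.45,
                             map_mean = 80.6, map_sd = 10,
                             seed = 1L) {
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  if (phase_sd_deg <= 0) abort("`phase_sd_deg` must be positive.")
  if (!all(segments %in% c("PRE", "POST", "2H"))) {
    abort("`segments` must be a subset of PRE, POST, 2H.")
  }
  if (outcome_good_fraction < 0 || outcome_good_fraction > 1) {
    abort("`outcome_good_fraction` must lie in [0, 1].")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), segments = segments,
      phase_mean_deg = phase_mean_deg, phase_sd_deg = phase_sd_deg,
      between_subject_sd_deg = between_subject_sd_deg,
      hemisphere_effect_deg = hemisphere_effect_deg,
      etco2_slope_deg_per_kpa = etco2_slope_deg_per_kpa,
      segment_slopes_deg = segment_slopes_deg,
      outcome_good_fraction = outcome_good_fraction,
      ss_phase_mean_deg = ss_phase_mean_deg,
      ss_phase_sd_deg = ss_phase_sd_deg, ss_effect = ss_effect,
      age_mean = age_mean, age_sd = age_sd,
      etco2_mean = etco2_mean, etco2_sd = etco2_sd,
      map_mean = map_mean, map_sd = map_sd,
      seed = as.integer(seed)
    ),
    class = "subject_sim_spec"
  )
}

#' Simulate an analysis table of per-subject TFA results
#'
#' Draws one row per subject x hemisphere x time segment (LF band) following
#' the generative model in [subject_sim_spec()]:
#' \deqn{phase = \mu + b_i + \delta\,[IH] + s_h (ETCO2_i - \bar{E}) +
#'   g_{grp(i)}\, k_{seg} + \lambda\, ss + \epsilon}
#' with subject intercept \eqn{b_i \sim N(0, \sigma_b^2)} and residual
#' \eqn{\epsilon \sim N(0, \sigma^2)}. Covariates and outcome labels (mRS,
#' independence = mRS < 3, mortality = mRS 6) are drawn per subject.
#'
#' @param spec A [subject_sim_spec()].
#' @return A tibble with columns `subject_id`, `hemisphere`, `segment`,
#'   `band`, `phase_deg`, `gain`, `coherence`, `ss_phase_deg`, `age`,
#'   `etco2`, `mean_abp`, `nihss`, `mrs`, `independence`, `mortality`,
#'   `aetiology`, `stenosis`, `recan_success`, `ivt`, `lkw_to_recan_h`,
#'   `outcome_group`.
#' @examples
#' tab <- synthesize_subject_table(subject_sim_spec(n_subjects = 6, seed = 2))
#' dplyr::count(tab, hemisphere, segment)
#' @export
synthesize_subject_table <- function(spec) {
  stopifnot(inherits(spec, "subject_sim_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n_subjects

  n_good <- round(n * spec$outcome_good_fraction)
  grp <- sample(c(rep("good", n_good), rep("poor", n - n_good)))
  mrs <- ifelse(grp == "good",
                sample(0:2, n, replace = TRUE),
                sample(3:6, n, replace = TRUE))

  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    b = rnorm(n, 0, spec$between_subject_sd_deg),
    age = rnorm(n, spec$age_mean, spec$age_sd),
    etco2 = rnorm(n, spec$etco2_mean, spec$etco2_sd),
    mean_abp = rnorm(n, spec$map_mean, spec$map_sd),
    nihss = pmin(30L, pmax(1L, round(rnorm(n, 14, 6)))),
    outcome_group = grp,
    mrs = as.integer(mrs),
    aetiology = sample(c("LAA", "CE", "other"), n, replace = TRUE,
                       prob = c(0.3, 0.5, 0.2)),
    stenosis = runif(n) < 0.3,
    recan_success = runif(n) < 0.85,
    ivt = runif(n) < 0.4,
    lkw_to_recan_h = exp(rnorm(n, log(5.4), 0.5))
  ) |>
    dplyr::mutate(independence = .data$mrs < 3,
                  mortality = .data$mrs == 6)

  seg_index <- c(PRE = 0, POST = 1, `2H` = 2)
  rows <- tidyr::expand_grid(
    subject_id = subjects$subject_id,
    hemisphere = c("ischaemic", "contralateral"),
    segment = spec$segments
  ) |>
    dplyr::left_join(subjects, by = "subject_id")

  slopes <- spec$etco2_slope_deg_per_kpa
  gslopes <- spec$segment_slopes_deg
  m <- nrow(rows)
  rows |>
    dplyr::mutate(
      band = "LF",
      ss_phase_deg = rnorm(m, spec$ss_phase_mean_deg, spec$ss_phase_sd_deg),
      phase_deg = spec$phase_mean_deg + .data$b +
        spec$hemisphere_effect_deg * (.data$hemisphere == "ischaemic") +
        unname(slopes[.data$hemisphere]) * (.data$etco2 - spec$etco2_mean) +
        (if (is.null(gslopes)) 0 else
          unname(gslopes[.data$outcome_group]) *
            seg_index[.data$segment]) +
        spec$ss_effect * .data$ss_phase_deg +
        rnorm(m, 0, spec$phase_sd_deg),
      gain = exp(rnorm(m, log(10), 0.4)),
      coherence = pmin(0.99, pmax(0.01, rnorm(m, 0.55, 0.15)))
    ) |>
    dplyr::select(
      "subject_id", "hemisphere", "segment", "band", "phase_deg", "gain",
      "coherence", "ss_phase_deg", "age", "etco2", "mean_abp", "nihss",
      "mrs", "independence", "mortality", "aetiology", "stenosis",
      "recan_success", "ivt", "lkw_to_recan_h", "outcome_group"
    )
}
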