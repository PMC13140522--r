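#' Paired side-to-side comparison of a TFA measure
#'
#' Compares the ischaemic and contralateral hemisphere within subjects for
#' one measure, band, and time segment. Per-subject differences
#' (ischaemic minus contralateral) are screened for normality with a
#' Shapiro-Wilk test at `alpha_normality`; a paired t-test is used when the
#' screen passes, a Wilcoxon signed-rank test otherwise. With zero-variance
#' differences (exactly constant side-to-side offset) the test degenerates:
#' the estimate is the constant offset and the p-value is reported as 0 for
#' a nonzero offset (below any representable threshold) or 1 otherwise.
#'
#' @param table An analysis table (see [synthesize_subject_table()]) with
#'   `subject_id`, `hemisphere`, and the measure column.
#' @param measure Measure column name (default `"phase_deg"`).
#' @param segment Optional segment filter (`"PRE"`, `"POST"`, `"2H"`).
#' @param band Optional band filter.
#' @param alpha_normality Significance level of the normality screen.
#' @return One-row tibble: `measure`, `segment`, `method`, `n_pairs`,
#'   `estimate` (mean difference), `statistic`, `p_value`.
#' @export
paired_side_test <- function(table, measure = "phase_deg", segment = NULL,
                             band = NULL, alpha_normality = 0.05) {
  tab <- table
  if (!is.null(segment)) tab <- dplyr::filter(tab, .data$segment == !!segment)
  if (!is.null(band) && "band" %in% names(tab)) {
    tab <- dplyr::filter(tab, .data$band == !!band)
  }
  wide <- tab |>
    dplyr::select("subject_id", "hemisphere", dplyr::all_of(measure)) |>
    tidyr::pivot_wider(names_from = "hemisphere",
                       values_from = dplyr::all_of(measure))
  if (!all(c("ischaemic", "contralateral") %in% names(wide))) {
    abort("Both hemispheres must be present for a paired comparison.")
  }
  wide <- wide[complete.cases(wide), ]
  if (nrow(wide) < 3) abort("Fewer than 3 complete hemisphere pairs.")
  d <- wide$ischaemic - wide$contralateral

  if (sd(d) < 1e-12) {
    est <- mean(d)
    return(tibble(measure = measure, segment = segment %||% NA_character_,
                  method = "degenerate (zero-variance differences)",
                  n_pairs = length(d), estimate = est,
                  statistic = NA_real_,
                  p_value = if (abs(est) > 0) 0 else 1))
  }

  normal <- shapiro.test(d)$p.value >= alpha_normality
  if (normal) {
    ht <- t.test(d)
    method <- "paired t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(d))
    method <- "Wilcoxon signed-rank"
  }
  tibble(measure = measure, segment = segment %||% NA_character_,
         method = method, n_pairs = length(d), estimate = mean(d),
         statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone non-decreasing in rank order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must be finite and lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Linear mixed-effects model of LF phase shift
#'
#' Fits a restricted-maximum-likelihood linear mixed model with a subject
#' random intercept to band-averaged phase-shift rows. The default fixed
#' structure is hemisphere plus the requested covariates with
#' hemisphere-by-covariate interactions, optionally the short-separation
#' channel TFA phase as a nuisance regressor, and — for sequential
#' (multi-segment) models — the time segment with segment-by-covariate and
#' segment-by-hemisphere interactions. Categorical fixed effects with any
#' level observed in fewer than `min_level_n` subjects are refused
#' (insufficient sample size for the level). Convergence and singularity
#' messages are captured and reported, never silently absorbed.
#'
#' @param table Analysis table with one row per subject x hemisphere x
#'   segment (x band), containing `phase_deg` (or `outcome`), `hemisphere`,
#'   `subject_id`, optionally `segment` and `ss_phase_deg`.
#' @param fixed Character vector of covariate column names.
#' @param sequential Add time-segment fixed effect and its interactions.
#' @param interactions Include hemisphere-by-covariate interactions.
#' @param ss_regressor Include `ss_phase_deg` as a fixed-effect regressor.
#' @param outcome Outcome column (default `"phase_deg"`).
#' @param formula Optional full `lme4` formula overriding the constructed
#'   one.
#' @param min_level_n Minimum subjects per level of a categorical fixed
#'   effect.
#' @param reml Use REML (default) or maximum likelihood.
#' @return An object of class `phase_lmm` with methods [tidy()],
#'   [glance()], [interaction_tests()], `print()` and `autoplot()`.
#' @examples
#' tab <- synthesize_subject_table(subject_sim_spec(n_subjects = 20, seed = 3))
#' fit <- fit_phase_lmm(tab, fixed = "etco2")
#' tidy(fit)
#' glance(fit)
#' @export
fit_phase_lmm <- function(table, fixed = character(), sequential = FALSE,
                          interactions = TRUE, ss_regressor = TRUE,
                          outcome = "phase_deg", formula = NULL,
                          min_level_n = 4, reml = TRUE) {
  dat <- as_tibble(table)
  dat$hemisphere <- factor(dat$hemisphere,
                           levels = c("contralateral", "ischaemic"))
  if ("segment" %in% names(dat)) {
    dat$segment <- factor(dat$segment, levels = c("PRE", "POST", "2H"))
    dat$segment <- droplevels(dat$segment)
  }

  # small-sample guardrail on categorical fixed effects
  for (v in fixed) {
    if (!v %in% names(dat)) abort(paste0("Fixed effect `", v, "` not in table."))
    x <- dat[[v]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      counts <- dat |>
        dplyr::distinct(.data$subject_id, .keep_all = TRUE) |>
        dplyr::count(.data[[v]])
      if (any(counts$n < min_level_n)) {
        abort(paste0("Fixed effect `", v, "` has a level with fewer than ",
                     min_level_n, " subjects; excluded per the sample-size rule."))
      }
    }
  }

  if (is.null(formula)) {
    rhs <- "hemisphere"
    for (v in fixed) {
      rhs <- paste(rhs, "+", v)
      if (interactions) rhs <- paste(rhs, "+ hemisphere:", v)
    }
    if (sequential) {
      rhs <- paste(rhs, "+ segment + segment:hemisphere")
      for (v in fixed) rhs <- paste(rhs, "+ segment:", v)
    }
    if (ss_regressor && "ss_phase_deg" %in% names(dat)) {
      rhs <- paste(rhs, "+ ss_phase_deg")
    }
    formula <- as.formula(paste(outcome, "~", rhs, "+ (1 | subject_id)"))
  }

  msgs <- character()
  fit <- tryCatch(withCallingHandlers(
    lmerTest::lmer(formula, data = dat, REML = reml,
                   control = lme4::lmerControl(calc.derivs = TRUE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  ), error = function(e) {
    abort(paste0("Mixed-model fit failed: ", conditionMessage(e)))
  })

  structure(
    list(fit = fit, formula = formula, data = dat, messages = msgs,
         singular = lme4::isSingular(fit),
         converged = !any(grepl("failed to converge", msgs))),
    class = "phase_lmm"
  )
}

#' @export
print.phase_lmm <- function(x, ...) {
  cat("<phase_lmm> ", deparse(x$formula), "\n", sep = "")
  cat("  ", nrow(x$data), " rows, ",
      dplyr::n_distinct(x$data$subject_id), " subjects",
      if (x$singular) ", singular fit" else "",
      if (!x$converged) ", CONVERGENCE WARNING" else "", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' Tidy fixed-effect estimates of a phase-shift mixed model
#'
#' One row per fixed effect with Satterthwaite degrees of freedom and
#' Wald-type confidence intervals `estimate ± t(df) * SE`.
#'
#' @param x A `phase_lmm` object.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std_error`, `df`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @method tidy phase_lmm
#' @export
tidy.phase_lmm <- function(x, conf.level = 0.95, ...) {
  co <- summary(x$fit)$coefficients
  tq <- qt(1 - (1 - conf.level) / 2, co[, "df"])
  tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    df = unname(co[, "df"]),
    statistic = unname(co[, "t value"]),
    p_value = unname(co[, "Pr(>|t|)"]),
    conf_low = unname(co[, "Estimate"] - tq * co[, "Std. Error"]),
    conf_high = unname(co[, "Estimate"] + tq * co[, "Std. Error"])
  )
}

#' Fit summaries of a phase-shift mixed model
#'
#' Reports variance components, marginal and conditional R-squared
#' (Nakagawa-Schielzeth: fixed-effect variance over total, and fixed plus
#' random over total), AIC, and convergence/singularity status.
#'
#' @param x A `phase_lmm` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance phase_lmm
#' @export
glance.phase_lmm <- function(x, ...) {
  fit <- x$fit
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- sum(vc$vcov[vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  var_fix <- var(as.numeric(predict(fit, re.form = NA)))
  tot <- var_fix + var_rand + var_res
  tibble(
    nobs = nrow(x$data),
    n_subjects = dplyr::n_distinct(x$data$subject_id),
    sd_subject = sqrt(var_rand),
    sigma = sqrt(var_res),
    r2_marginal = var_fix / tot,
    r2_conditional = (var_fix + var_rand) / tot,
    aic = AIC(fit),
    log_lik = as.numeric(logLik(fit)),
    singular = x$singular,
    converged = x$converged
  )
}

#' F-tests of the fixed-effect terms of a phase-shift mixed model
#'
#' Type III tests with Satterthwaite denominator degrees of freedom.
#'
#' @param x A `phase_lmm` object.
#' @return Tibble: `term`, `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
interaction_tests <- function(x) {
  stopifnot(inherits(x, "phase_lmm"))
  an <- anova(x$fit, type = 3)
  tibble(
    term = rownames(an),
    f_statistic = an[, "F value"],
    df1 = an[, "NumDF"],
    df2 = an[, "DenDF"],
    p_value = an[, "Pr(>F)"]
  )
}
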