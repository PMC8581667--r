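# Synthetic survival cohort generator: log-normal density feature, binary
# high/low group at the cohort mean, exponential event times whose hazard
# depends on the group, uniform censoring.

#' Specification of a synthetic survival cohort
#'
#' The index density feature (e.g. PD-1+ helper T cell density in tumor
#' cell nests, cells/mm^2) is log-normal; patients at or above the cohort
#' mean form the high-density group, whose log hazard is shifted by
#' `log_hazard_beta`. Event times are exponential in continuous months;
#' censoring times are uniform on `(0, u)` with the horizon `u` solved so
#' that the expected censoring fraction under the baseline hazard matches
#' `censor_rate`.
#'
#' @param n_patients Number of patients.
#' @param density_log_mean,density_log_sd Log-scale mean and SD of the
#'   index density feature.
#' @param log_hazard_beta True log hazard ratio of high vs low group.
#' @param baseline_hazard_per_month Baseline exponential hazard (1/months).
#' @param censor_rate Target censoring fraction in \[0, 1\].
#' @param extra_covariates Named prevalences in \[0, 1\] of independent
#'   binary covariates with no effect on the hazard (defaults emulate a
#'   clinical covariate block: HPV status, sex, smoking, stage).
#' @param index_feature Column name for the density feature.
#' @param round_months If TRUE, round times to whole months (introduces
#'   ties, exercising tie handling in Cox fits).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 51L,
                            density_log_mean = log(40), density_log_sd = 1,
                            log_hazard_beta = log(3),
                            baseline_hazard_per_month = 0.015,
                            censor_rate = 0.5,
                            extra_covariates = c(hpv_negative = 0.3,
                                                 male = 0.85,
                                                 smoking_history = 0.6,
                                                 stage_3_4 = 0.55),
                            index_feature = "pd1_helper_nest",
                            round_months = FALSE,
                            seed = 1L) {
  stopifnot(n_patients >= 1, baseline_hazard_per_month > 0,
            censor_rate >= 0, censor_rate <= 1, density_log_sd >= 0,
            all(extra_covariates >= 0), all(extra_covariates <= 1))
  structure(list(n_patients = as.integer(n_patients),
                 density_log_mean = density_log_mean,
                 density_log_sd = density_log_sd,
                 log_hazard_beta = log_hazard_beta,
                 baseline_hazard_per_month = baseline_hazard_per_month,
                 censor_rate = censor_rate,
                 extra_covariates = extra_covariates,
                 index_feature = index_feature,
                 round_months = isTRUE(round_months),
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# Horizon u of Uniform(0, u) censoring such that P(C < T) = rate for
# T ~ Exp(lambda): P(T > C) = (1 - exp(-lambda u)) / (lambda u).
censor_horizon <- function(lambda, rate) {
  if (rate <= 0) return(Inf)
  if (rate >= 1) return(.Machine$double.eps)
  f <- function(u) (1 - exp(-lambda * u)) / (lambda * u) - (1 - rate)
  uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Generate a synthetic survival cohort
#'
#' @param spec A `cohort_sim_spec`.
#' @return A data frame of class `cohort_table`: `patient_id`, the index
#'   density feature, `group_high` (density at or above the cohort mean),
#'   the extra binary covariates, `time_months` (> 0) and `event`
#'   (TRUE = death observed). Deterministic under the spec seed.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  density <- rlnorm(n, spec$density_log_mean, spec$density_log_sd)
  group_high <- density >= mean(density)
  hazard <- spec$baseline_hazard_per_month *
    exp(spec$log_hazard_beta * group_high)
  t_event <- rexp(n, hazard)
  u <- censor_horizon(spec$baseline_hazard_per_month, spec$censor_rate)
  t_censor <- if (is.finite(u)) runif(n, 0, u) else rep(Inf, n)
  time <- pmin(t_event, t_censor)
  event <- t_event <= t_censor
  if (spec$round_months) time <- pmax(round(time), 1)
  time <- pmax(time, .Machine$double.eps)
  tab <- data.frame(patient_id = seq_len(n))
  tab[[spec$index_feature]] <- density
  tab$group_high <- group_high
  for (cv in names(spec$extra_covariates))
    tab[[cv]] <- runif(n) < spec$extra_covariates[[cv]]
  tab$time_months <- time
  tab$event <- event
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
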