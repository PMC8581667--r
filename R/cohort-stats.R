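# Cohort-level statistics: Kaplan-Meier, log-rank, Cox PH (survival
# package backend), Spearman matrices, paired/unpaired rank tests, and
# cutoff-based stratification (mean / median / fixed value / ROC-Youden).

#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator; censored times reduce the risk set without
#' introducing steps. The curve invariants S(0) = 1 and monotone
#' non-increase are asserted on every fit.
#'
#' @param time Positive event/censoring times (months).
#' @param event Logical, TRUE = death observed.
#' @return An object of class `km_curve`: data frame columns `time`,
#'   `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  if (any(out$survival > 1 + 1e-12) || is.unsorted(rev(out$survival)))
    stop("internal error: KM curve must start at 1 and be non-increasing")
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival time from a KM curve
#'
#' Smallest event time at which the estimated survival drops to 0.5 or
#' below; NA when the curve never reaches 0.5.
#'
#' @param curve A `km_curve`.
#' @return Scalar months (or NA).
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  i <- which(curve$survival <= 0.5)
  if (!length(i)) NA_real_ else curve$time[min(i)]
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square comparing two
#' survival curves; p from the chi-square upper tail.
#'
#' @param time,event Survival outcome per patient.
#' @param group Two-level grouping (logical or factor-like).
#' @return `list(statistic, p, df = 1)`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("log-rank test requires exactly two groups")
  if (sum(event) == 0)
    stop("no events in either group: log-rank test undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ g)
  stat <- sd$chisq
  list(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE), df = 1L)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default)
#' and reports per-covariate hazard ratios with Wald 95% confidence
#' intervals and p-values. Monotone-likelihood / separation problems are
#' flagged as non-convergence instead of reporting unstable hazard ratios.
#'
#' @param cohort A data frame (e.g. a `cohort_table`) with `time_months`
#'   and `event` columns.
#' @param covariates Column names entering the model jointly.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_result`: data frame with `covariate`,
#'   `hr`, `ci_low`, `ci_high`, `p`, plus attributes `converged` and
#'   `ties`.
#' @export
cox_fit <- function(cohort, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time_months", "event") %in% names(cohort)),
            all(covariates %in% names(cohort)), length(covariates) >= 1)
  if (sum(cohort$event) < 2) stop("fewer than 2 events: model unidentified")
  for (cv in covariates)
    if (length(unique(cohort[[cv]])) < 2L)
      stop("constant covariate: ", cv)
  X <- as.data.frame(lapply(cohort[covariates], function(v)
    if (is.logical(v)) as.integer(v) else v))
  dat <- cbind(data.frame(time = cohort$time_months,
                          status = as.integer(cohort$event)), X)
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(covariates, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50L)),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  beta <- s$coefficients[, "coef"]
  se <- s$coefficients[, "se(coef)"]
  if (any(!is.finite(beta)) || any(abs(beta) > 15)) converged <- FALSE
  out <- data.frame(covariate = covariates,
                    hr = exp(beta),
                    ci_low = exp(beta - 1.959964 * se),
                    ci_high = exp(beta + 1.959964 * se),
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  attr(out, "converged") <- converged
  attr(out, "ties") <- ties
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Spearman correlation matrix of per-patient features
#'
#' Rank correlation per feature pair with average-rank tie handling;
#' symmetric with unit diagonal. A constant feature has no rank variance
#' and its correlations are reported as NA.
#'
#' @param features Numeric data frame or matrix, one row per patient
#'   (at least 3).
#' @return Symmetric correlation matrix.
#' @export
spearman_matrix <- function(features) {
  X <- as.matrix(features)
  stopifnot(is.numeric(X), nrow(X) >= 3)
  R <- suppressWarnings(cor(X, method = "spearman"))
  diag(R) <- 1
  R
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped; the p-value is exact for n <= 25
#' remaining pairs and uses the normal approximation with continuity
#' correction otherwise.
#'
#' @param paired_a,paired_b Equal-length paired measurements.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return `list(statistic = V, p, n_used, exact)`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_max = 25L) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0)
    stop("all paired differences are zero: test degenerate", call. = FALSE)
  if (length(d) < 5)
    stop("fewer than 5 non-zero differences", call. = FALSE)
  exact <- length(d) <= exact_max && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n_used = length(d), exact = exact)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction; p from the chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param groups List of 2 or more numeric vectors.
#' @return `list(statistic = H, p, df)`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 1),
            sum(vapply(groups, length, 1L)) >= 5)
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L)
    stop("all values identical: test degenerate", call. = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- stats::kruskal.test(vals, g)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Cutoff rule for dichotomizing a density feature
#'
#' @param kind `"mean"`, `"median"`, `"fixed"` or `"roc_youden"`.
#' @param fixed_value Required iff `kind = "fixed"` (e.g. 43.1 cells/mm^2,
#'   a discovery-cohort cutoff carried into validation).
#' @return An object of class `cutoff_rule`.
#' @export
cutoff_rule <- function(kind = c("mean", "median", "fixed", "roc_youden"),
                        fixed_value = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed" && is.null(fixed_value))
    stop("fixed cutoff rule requires fixed_value")
  if (kind != "fixed" && !is.null(fixed_value))
    stop("fixed_value is only meaningful for kind = 'fixed'")
  structure(list(kind = kind, fixed_value = fixed_value),
            class = "cutoff_rule")
}

#' Dichotomize a feature into high/low groups
#'
#' High means value at or above the cutoff. The cutoff is the arithmetic
#' mean, the median, a fixed value, or the ROC operating point maximizing
#' Youden's J (sensitivity + specificity - 1) against the event label,
#' with higher values treated as event-associated; for the ROC rule the
#' smallest optimal threshold is taken so the choice is deterministic.
#'
#' @param values Per-patient feature values.
#' @param rule A `cutoff_rule`.
#' @param events Logical event labels, required iff `rule$kind ==
#'   "roc_youden"`.
#' @return `list(high = <logical>, cutoff = <value used>)`.
#' @export
dichotomize <- function(values, rule, events = NULL) {
  stopifnot(inherits(rule, "cutoff_rule"), is.numeric(values))
  cutoff <- switch(rule$kind,
    mean = mean(values),
    median = median(values),
    fixed = rule$fixed_value,
    roc_youden = {
      if (is.null(events)) stop("roc_youden rule requires event labels")
      if (length(unique(events)) < 2L)
        stop("single-class events: ROC undefined", call. = FALSE)
      r <- pROC::roc(response = as.integer(events), predictor = values,
                     levels = c(0, 1), direction = "<", quiet = TRUE)
      co <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
      min(co$threshold)
    })
  list(high = values >= cutoff, cutoff = cutoff)
}

#' Two-marker stratification (both-high versus other)
#'
#' Labels each patient `"both_high"` when high under both features' rules
#' (e.g. PD-1+ helper T density at the mean cutoff and CD163+ TAM density
#' at the median cutoff) and `"other"` otherwise, for downstream KM /
#' log-rank comparison.
#'
#' @param cohort Data frame of per-patient features.
#' @param feature_a,feature_b Feature column names.
#' @param rule_a,rule_b `cutoff_rule`s for the two features.
#' @param events Event labels, needed when either rule is ROC-based.
#' @return `list(labels = <character>, cutoff_a, cutoff_b)`.
#' @export
two_marker_strata <- function(cohort, feature_a, rule_a, feature_b, rule_b,
                              events = NULL) {
  stopifnot(all(c(feature_a, feature_b) %in% names(cohort)))
  da <- dichotomize(cohort[[feature_a]], rule_a, events)
  db <- dichotomize(cohort[[feature_b]], rule_b, events)
  list(labels = ifelse(da$high & db$high, "both_high", "other"),
       cutoff_a = da$cutoff, cutoff_b = db$cutoff)
}
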