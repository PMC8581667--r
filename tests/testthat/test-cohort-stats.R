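# Survival statistics, rank tests and cutoff stratification.

test_that("KM estimator matches closed forms on tiny cohorts", {
  all_cens <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(all_cens$survival == 1))
  two <- km_estimate(c(1, 2), c(TRUE, TRUE))
  expect_equal(two$survival, c(0.5, 0))
  # censoring reduces the risk set without a step
  mix <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(mix$survival[mix$time == 1], 2 / 3)
  expect_equal(mix$survival[mix$time == 3], 0)
})

test_that("KM median converges to the exponential closed form", {
  lambda <- 0.08
  coh <- exp_cohort(5000, lambda, seed = 31)
  med <- km_median(km_estimate(coh$time_months, coh$event))
  expect_lt(abs(med - log(2) / lambda) / (log(2) / lambda), 0.05)
})

test_that("log-rank test is zero for identical groups and matches a permutation null", {
  t1 <- c(2, 4, 6, 8, 10); e1 <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  lr0 <- logrank_test(c(t1, t1), c(e1, e1), rep(c(0, 1), each = 5))
  expect_lt(lr0$statistic, 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-6)
  # 6-patient worked example (mixed censoring) vs permutation oracle
  time <- c(3.7, 4.4, 11.9, 12.8, 25.6, 27)
  event <- c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  group <- c(0, 0, 1, 0, 1, 1)
  obs <- logrank_test(time, event, group)
  set.seed(32)
  perm <- replicate(5000, {
    g <- sample(group)
    logrank_test(time, event, g)$statistic
  })
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.02)
  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c(0, 1)), "no events")
})

test_that("Cox fit recovers null and non-null hazard ratios", {
  spec <- cohort_sim_spec(n_patients = 2000, log_hazard_beta = 0,
                          censor_rate = 0, seed = 33)
  coh <- generate_cohort(spec)
  fit <- cox_fit(coh, "group_high")
  expect_lt(abs(log(fit$hr)), 0.1)
  expect_true(attr(fit, "converged"))
  spec3 <- cohort_sim_spec(n_patients = 2000, log_hazard_beta = log(3),
                           censor_rate = 0, seed = 34)
  fit3 <- cox_fit(generate_cohort(spec3), "group_high")
  expect_gte(fit3$hr, 2.6)
  expect_lte(fit3$hr, 3.5)
  expect_true(fit3$ci_low <= fit3$hr && fit3$hr <= fit3$ci_high)
})

test_that("Cox flags separation instead of reporting unstable estimates", {
  coh <- data.frame(time_months = c(1, 2, 3, 10, 11, 12),
                    event = rep(TRUE, 6),
                    bad = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  fit <- cox_fit(coh, "bad")
  expect_false(attr(fit, "converged"))
})

test_that("Cox score test approximates the log-rank statistic without ties", {
  spec <- cohort_sim_spec(n_patients = 150, log_hazard_beta = log(2),
                          censor_rate = 0.3, seed = 35)
  coh <- generate_cohort(spec)
  lr <- logrank_test(coh$time_months, coh$event, coh$group_high)
  sc <- survival::coxph(
    survival::Surv(coh$time_months, coh$event) ~ coh$group_high)$score
  expect_lt(abs(lr$statistic - sc) / lr$statistic, 0.02)
})

test_that("Spearman matrix is monotone-invariant, symmetric, NA for constants", {
  x <- c(0.3, 1.2, 2.4, 3.1, 4.8, 5.2, 6.9)
  f <- data.frame(x = x, cube = x^3, neg = -x, const = rep(2, 7))
  R <- spearman_matrix(f)
  expect_equal(R["x", "cube"], 1.0)
  expect_equal(R["x", "neg"], -1.0)
  expect_true(is.na(R["x", "const"]))
  expect_equal(R, t(R))
  set.seed(36)
  g <- data.frame(a = rnorm(1000), b = rnorm(1000))
  expect_lt(abs(spearman_matrix(g)["a", "b"]), 0.1)
})

test_that("Wilcoxon signed-rank exact p equals full sign enumeration (n = 8)", {
  a <- c(12.1, 9.8, 14.2, 8.1, 11.3, 10.2, 13.4, 9.1)
  b <- c(10.0, 9.1, 11.9, 8.9, 10.1, 9.7, 11.8, 10.0)
  res <- wilcoxon_signed_rank(a, b)
  expect_true(res$exact)
  d <- a - b
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  # enumerate all 2^8 sign assignments of the ranks
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  v_all <- signs %*% r
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  p_enum <- min(1, 2 * min(p_lo, p_hi))
  expect_equal(res$p, p_enum)
  expect_equal(res$statistic, v_obs)
})

test_that("Wilcoxon handles degenerate and shifted pairs", {
  a <- 1:10
  expect_error(wilcoxon_signed_rank(a, a), "zero")
  set.seed(37)
  base <- rnorm(20)
  res <- wilcoxon_signed_rank(base + 1, base)
  expect_lt(res$p, 0.01)
})

test_that("Kruskal-Wallis matches the direct rank formula on a 3-group fixture", {
  g <- list(c(27, 2, 4, 18, 7, 9), c(20, 8, 14, 36, 21, 22),
            c(34, 31, 3, 23, 30, 6))
  res <- kruskal_wallis(g)
  # direct formula (no ties in this fixture):
  # H = 12 / (N (N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  vals <- unlist(g)
  N <- length(vals)
  rk <- rank(vals)
  idx <- rep(seq_along(g), lengths(g))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, idx, function(r) length(r) * (mean(r) - (N + 1) / 2)^2))
  expect_equal(res$statistic, H, tolerance = 1e-12)
  expect_equal(res$df, 2)
  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_lt(kruskal_wallis(same)$statistic, 1e-10)
  expect_error(kruskal_wallis(list(rep(1, 4), rep(1, 4))), "identical")
})

test_that("chi-square p of Kruskal-Wallis is close to a permutation p", {
  g <- list(c(5, 8, 11, 2), c(9, 12, 14, 13), c(1, 3, 6, 7))
  res <- kruskal_wallis(g)
  vals <- unlist(g)
  sizes <- lengths(g)
  set.seed(38)
  perm <- replicate(5000, {
    v <- sample(vals)
    kruskal_wallis(split(v, rep(seq_along(sizes), sizes)))$statistic
  })
  expect_lt(abs(res$p - mean(perm >= res$statistic - 1e-12)), 0.02)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(39)
  a <- rlnorm(12); b <- rlnorm(12) * 1.4
  w1 <- wilcoxon_signed_rank(a, b)
  # monotone transform of the differences is not meaningful for paired
  # tests; invariance holds for the unpaired rank statistics
  k1 <- kruskal_wallis(list(a, b))
  k2 <- kruskal_wallis(list(log(a), log(b)))
  expect_equal(k1$statistic, k2$statistic)
  f <- data.frame(a = a, b = b)
  expect_equal(spearman_matrix(f)["a", "b"],
               spearman_matrix(exp(f))["a", "b"])
  expect_true(is.list(w1))
})

test_that("cutoff rules dichotomize as documented", {
  d <- dichotomize(c(1, 2, 3, 4), cutoff_rule("mean"))
  expect_equal(d$cutoff, 2.5)
  expect_equal(d$high, c(FALSE, FALSE, TRUE, TRUE))
  dm <- dichotomize(c(1, 2, 3, 4, 100), cutoff_rule("median"))
  expect_equal(dm$cutoff, 3)
  expect_equal(sum(dm$high), 3)  # high includes the cutoff value
  df <- dichotomize(c(10, 50, 80), cutoff_rule("fixed", 43.1))
  expect_equal(df$cutoff, 43.1)
  expect_equal(df$high, c(FALSE, TRUE, TRUE))
  expect_error(cutoff_rule("fixed"), "fixed_value")
})

test_that("Youden cutoff attains J = 1 for a separable feature", {
  values <- c(1, 2, 3, 10, 11, 12)
  events <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  d <- dichotomize(values, cutoff_rule("roc_youden"), events)
  sens <- sum(d$high & events) / sum(events)
  spec <- sum(!d$high & !events) / sum(!events)
  expect_equal(sens + spec - 1, 1)
  expect_error(dichotomize(values, cutoff_rule("roc_youden"),
                           rep(TRUE, 6)), "single-class")
})

test_that("two-marker stratification labels both-high patients", {
  coh <- data.frame(pd1_helper_nest = c(100, 100, 10, 10),
                    cd163_tam_nest = c(50, 5, 50, 5))
  st <- two_marker_strata(coh, "pd1_helper_nest", cutoff_rule("mean"),
                          "cd163_tam_nest", cutoff_rule("median"))
  expect_equal(st$labels, c("both_high", "other", "other", "other"))
})

test_that("both-high interaction cohorts reach log-rank significance", {
  set.seed(40)
  n <- 200
  fa <- rlnorm(n); fb <- rlnorm(n)
  both <- fa >= mean(fa) & fb >= median(fb)
  time <- rexp(n, 0.02 * exp(log(3) * both))
  coh <- data.frame(fa = fa, fb = fb, time_months = time,
                    event = rep(TRUE, n))
  st <- two_marker_strata(coh, "fa", cutoff_rule("mean"),
                          "fb", cutoff_rule("median"))
  lr <- logrank_test(coh$time_months, coh$event, st$labels)
  expect_lt(lr$p, 0.05)
})
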