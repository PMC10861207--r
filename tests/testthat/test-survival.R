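test_that("km_estimate matches the product-limit estimator by hand", {
  # four deaths, no censoring: uniform steps
  et <- event_table(paste0("w", 1:4), "g", c(1, 2, 3, 4), 1)
  km <- km_estimate(et)
  expect_equal(km$times, c(1, 2, 3, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_at_risk, c(4, 3, 2, 1))
  expect_true(km$fully_observed)

  # death@1, censor@2, death@3: S(1) = 2/3, S(3) = (2/3)*(1 - 1/1) = 0
  et2 <- event_table(paste0("w", 1:3), "g", c(1, 2, 3), c(1, 0, 1))
  km2 <- km_estimate(et2)
  expect_equal(km2$times, c(1, 3))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_true(km2$fully_observed)

  # all censored: S stays at 1, not fully observed
  et3 <- event_table(paste0("w", 1:3), "g", c(5, 6, 7), 0)
  km3 <- km_estimate(et3)
  expect_length(km3$times, 0)
  expect_false(km3$fully_observed)
  expect_equal(km3$t_end, 7)
})

test_that("km_estimate rejects bad input", {
  expect_error(event_table("a", "g", -1, 1), "negative")
  et <- toy_events()
  expect_error(km_estimate(et), "groups")
  expect_silent(km_estimate(et, group = "control"))
  expect_error(subset_group(et, "nope"), "no subjects")
})

test_that("curve_auc integrates the step function exactly", {
  et <- event_table(paste0("w", 1:4), "g", c(1, 2, 3, 4), 1)
  km <- km_estimate(et)
  expect_equal(curve_auc(km), 2.5)          # sample mean of death times
  expect_equal(curve_auc(km, t_max = 0), 0) # zero-width interval
  expect_equal(curve_auc(km, t_max = 0.5), 0.5) # S = 1 before first event
  expect_equal(curve_auc(km, t_max = 1.5), 1 + 0.75 * 0.5)

  # all-censored curve integrates S = 1 up to t_end (restricted mean)
  cens <- km_estimate(event_table(paste0("w", 1:3), "g", c(10, 10, 10), 0))
  expect_equal(curve_auc(cens), 10)

  # cross-check against the survival package's restricted mean
  set.seed(7)
  et2 <- event_table(paste0("w", 1:40), "g", rexp(40, 0.2),
                     rbinom(40, 1, 0.8))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(et2))
  rmean <- summary(fit, rmean = max(et2$time))$table[["rmean"]]
  expect_equal(curve_auc(km_estimate(et2)), unname(rmean), tolerance = 1e-10)
})

test_that("with no censoring curve_auc equals the mean death time exactly", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:60, 1)
    times <- round(rexp(n, 0.1), 3)
    et <- event_table(paste0("w", 1:n), "g", times, 1)
    expect_equal(curve_auc(km_estimate(et)), mean(times), tolerance = 1e-12)
  }
})

test_that("time-unit scaling scales AUCs and leaves S/L unchanged", {
  et <- toy_events()
  for (c_scale in c(0.5, 24, 3.7)) {
    scaled <- et
    scaled$time <- scaled$time * c_scale
    a0 <- curve_auc(km_estimate(et, "stress"))
    a1 <- curve_auc(km_estimate(scaled, "stress"))
    expect_equal(a1, c_scale * a0, tolerance = 1e-12)
    r0 <- s_over_l(km_estimate(et, "stress"), km_estimate(et, "control"))
    r1 <- s_over_l(km_estimate(scaled, "stress"),
                   km_estimate(scaled, "control"))
    expect_equal(r1$s_over_l, r0$s_over_l, tolerance = 1e-12)
  }
})

test_that("s_over_l classifies loss, neutral and gain", {
  et <- toy_events()
  stress <- km_estimate(et, "stress")
  control <- km_estimate(et, "control")

  res <- s_over_l(stress, control)
  expect_equal(res$s_over_l, res$auc_stress / res$auc_life)
  expect_lt(res$s_over_l, 1)               # left-shifted curve = loss
  expect_identical(res$classification, "loss")

  same <- s_over_l(control, control)
  expect_equal(same$s_over_l, 1)
  expect_identical(same$classification, "neutral")

  gain <- s_over_l(control, stress)
  expect_identical(gain$classification, "gain")
})

test_that("s_over_l recovers the inverse hazard ratio on exponential cohorts", {
  n <- 5000
  ctl <- simulate_cohort(n, rate = 0.1, seed = 101, group = "control")
  str <- simulate_cohort(n, rate = 0.2, seed = 202, group = "stress")
  res <- s_over_l(km_estimate(str), km_estimate(ctl))
  # population ratio of means: (1/0.2) / (1/0.1) = 0.5
  expect_lt(abs(res$s_over_l - 0.5), 0.05)
  # oracle: with no censoring each AUC is the cohort's sample mean
  expect_equal(res$s_over_l, mean(str$time) / mean(ctl$time),
               tolerance = 1e-12)
})

test_that("s_over_l errors on zero control AUC and unit mismatch", {
  et <- toy_events()
  ctl <- km_estimate(et, "control")
  zero <- km_estimate(event_table(c("a", "b"), "g", c(0, 0), 1))
  expect_error(s_over_l(ctl, zero), "zero")
  hrs <- event_table(paste0("h", 1:4), "g", 1:4, 1, unit = "hours")
  expect_error(s_over_l(km_estimate(hrs), ctl), "unit mismatch")
})

test_that("bootstrap CI contains the estimate and narrows with n", {
  widths <- vapply(c(50, 500, 5000), function(n) {
    ctl <- simulate_cohort(n, rate = 0.1, seed = 11, group = "control")
    str <- simulate_cohort(n, rate = 0.2, seed = 12, group = "stress")
    res <- s_over_l(km_estimate(str), km_estimate(ctl), n_boot = 200,
                    seed = 99,
                    source_events = list(stress = str, control = ctl))
    expect_true(res$ci_low <= res$s_over_l && res$s_over_l <= res$ci_high)
    res$ci_high - res$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # no source events -> no interval; bootstrap without a seed is an error
  et <- toy_events()
  res <- s_over_l(km_estimate(et, "stress"), km_estimate(et, "control"))
  expect_true(is.na(res$ci_low) && is.na(res$ci_high))
  expect_error(
    s_over_l(km_estimate(et, "stress"), km_estimate(et, "control"),
             source_events = list(stress = subset_group(et, "stress"),
                                  control = subset_group(et, "control"))),
    "seed")
})

test_that("delta_auc_pct computes relative survival gain", {
  et <- toy_events()
  ctl <- km_estimate(et, "control")
  expect_equal(delta_auc_pct(ctl, ctl), 0)
  expect_equal(delta_auc_pct(13, 10), 30)
  expect_equal(delta_auc_pct(0.45, 0.31), 1400 / 31)  # ~ +45%
  expect_error(delta_auc_pct(1, 0), "zero")
})

test_that("logrank_test agrees with the risk-set tabulation oracle", {
  g1 <- event_table(paste0("a", 1:2), "a", c(1, 2), 1)
  g2 <- event_table(paste0("b", 1:2), "b", c(3, 4), 1)
  res <- logrank_test(g1, g2)
  # hand tabulation gives (O - E)^2 / V = (7/6)^2 / (17/36) = 49/17
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(res$statistic, oracle_logrank(g1$time, g1$event,
                                             g2$time, g2$event),
               tolerance = 1e-10)

  # identical groups: statistic ~ 0, p ~ 1
  same <- logrank_test(g1, g1)
  expect_lt(same$statistic, 1e-10)
  expect_gt(same$p_value, 0.999)

  # complete separation is overwhelmingly significant
  ga <- event_table(paste0("a", 1:50), "a", 1:50, 1)
  gb <- event_table(paste0("b", 1:50), "b", 101:150, 1)
  sep <- logrank_test(ga, gb)
  expect_lt(sep$p_value, 0.001)
  expect_equal(sep$statistic, oracle_logrank(ga$time, ga$event,
                                             gb$time, gb$event),
               tolerance = 1e-8)

  # censored data still matches the oracle
  set.seed(5)
  gc1 <- event_table(paste0("c", 1:30), "c", rexp(30, 0.1),
                     rbinom(30, 1, 0.7))
  gc2 <- event_table(paste0("d", 1:30), "d", rexp(30, 0.2),
                     rbinom(30, 1, 0.7))
  expect_equal(logrank_test(gc1, gc2)$statistic,
               oracle_logrank(gc1$time, gc1$event, gc2$time, gc2$event),
               tolerance = 1e-8)

  none <- event_table(c("x", "y"), "g", c(1, 2), 0)
  expect_error(logrank_test(none, none), "at least one event")
})

test_that("dose_resilience_profile classifies and summarises records", {
  rec <- data.frame(study_id = "s1", dose = 50, stress_mean_span = 5,
                    control_mean_lifespan = 10)
  prof <- dose_resilience_profile(rec, c(0, 100))
  expect_equal(prof$median_sl, 0.5)
  expect_equal(prof$n_loss, 1)
  expect_equal(prof$n_gain, 0)

  # stress span equal to life span everywhere: median 1, zero loss
  rec2 <- data.frame(study_id = paste0("s", 1:5), dose = c(1, 5, 10, 50, 100),
                     stress_mean_span = 7, control_mean_lifespan = 7)
  prof2 <- dose_resilience_profile(rec2, c(0, 10, 100))
  expect_true(all(prof2$median_sl == 1))
  expect_true(all(prof2$n_loss == 0))

  # 100 uniform(0.2, 0.8) ratios in one bin: all loss, median near 0.5
  set.seed(31)
  sl <- runif(100, 0.2, 0.8)
  rec3 <- data.frame(study_id = paste0("s", 1:100), dose = 50,
                     stress_mean_span = sl * 20, control_mean_lifespan = 20)
  prof3 <- dose_resilience_profile(rec3, c(0, 100))
  expect_equal(prof3$n_loss, 100)
  expect_gt(prof3$median_sl, 0.4)
  expect_lt(prof3$median_sl, 0.6)
  expect_equal(prof3$median_sl, median(sl), tolerance = 1e-12)

  bad <- data.frame(study_id = "zz", dose = 1, stress_mean_span = 5,
                    control_mean_lifespan = 0)
  expect_warning(expect_error(dose_resilience_profile(bad, c(0, 10))),
                 "rejected")
  expect_error(dose_resilience_profile(rec, c(0, 10)), "cover")
})
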