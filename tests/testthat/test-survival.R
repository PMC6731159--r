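test_that("apply_exclusions removes chemotherapy and incomplete rows", {
  coh <- data.frame(chemotherapy = c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0),
                    ihc4 = c(1:9, NA), time_years = 1, event = 0)
  out <- apply_exclusions(coh)
  expect_equal(nrow(out), 7L)
  out2 <- apply_exclusions(coh, required = "ihc4")
  expect_equal(nrow(out2), 6L)
  ex <- attr(out2, "exclusions")
  expect_equal(unname(ex["input"]), 10L)
  expect_equal(unname(ex["chemotherapy"]), 3L)
  expect_equal(unname(ex["incomplete"]), 1L)
  expect_equal(unname(ex["input"]),
               unname(ex["chemotherapy"] + ex["incomplete"] + ex["analyzed"]))
  # no chemo recipients: unchanged
  none <- data.frame(chemotherapy = 0, ihc4 = 1:5, time_years = 1, event = 0)
  expect_equal(nrow(apply_exclusions(none)), 5L)
  expect_error(apply_exclusions(data.frame(chemotherapy = 1, time_years = 1)),
               "every patient")
  # synthetic preset: ~7% of 2498 excluded
  coh <- generate_cohort(cohort_config(n_patients = 2498, seed = 40))
  ex <- attr(apply_exclusions(coh), "exclusions")
  expect_lt(abs(ex[["chemotherapy"]] - 175), 45)
})

test_that("truncate_at_10y recodes post-horizon records as censored", {
  coh <- data.frame(time_years = c(12.3, 4.0, 10.0), event = c(1L, 1L, 1L))
  out <- truncate_at_10y(coh)
  expect_equal(out$time_years, c(10, 4, 10))
  expect_equal(out$event, c(0L, 1L, 1L))
  expect_error(truncate_at_10y(data.frame(time_years = c(3, 0), event = 0)),
               "positive")
  # the KM estimate at 10y is unaffected by what happened after 10y
  withr::with_seed(60, {
    raw <- data.frame(time_years = rexp(400, 0.08),
                      event = rbinom(400, 1, 0.8),
                      g = rep(c("a", "b"), 200))
  })
  km_raw <- km_logrank(truncate_at_10y(raw), "g")
  raw2 <- raw
  raw2$time_years[raw2$time_years > 10] <- raw2$time_years[raw2$time_years > 10] + 5
  km_mod <- km_logrank(truncate_at_10y(raw2), "g")
  expect_equal(km_raw$curves, km_mod$curves)
})

test_that("fit_cox matches the brute-force Efron oracle", {
  fx <- six_patient_fixture()
  fit <- fit_cox(fx, "x")
  expect_equal(fit$terms$coef, oracle_efron_mle(fx$time_years, fx$event, fx$x),
               tolerance = 1e-6)
  expect_equal(fit$loglik,
               oracle_efron_loglik(fit$terms$coef, fx$time_years, fx$event, fx$x),
               tolerance = 1e-9)
  expect_equal(fit$lr_chisq,
               2 * (fit$loglik -
                      oracle_efron_loglik(0, fx$time_years, fx$event, fx$x)),
               tolerance = 1e-9)
  # random small fixtures, with tied event times exercising the Efron terms
  withr::with_seed(71, {
    for (i in 1:25) {
      n <- sample(5:8, 1)
      d <- data.frame(time_years = sample(1:4, n, replace = TRUE),
                      event = rbinom(n, 1, 0.7),
                      x = round(rnorm(n), 2))
      if (sum(d$event) < 2 || sd(d$x) == 0) next
      fit <- try(suppressWarnings(fit_cox(d, "x")), silent = TRUE)
      if (inherits(fit, "try-error")) next       # separation etc.
      if (abs(fit$terms$coef) > 8) next          # monotone likelihood
      expect_equal(fit$terms$coef,
                   oracle_efron_mle(d$time_years, d$event, d$x),
                   tolerance = 1e-6)
    }
  })
})

test_that("fit_cox validates its inputs", {
  fx <- six_patient_fixture()
  fx$const <- 2
  expect_error(fit_cox(fx, "const"), "constant")
  fx$event <- 0L
  expect_error(fit_cox(fx, "x"), "no events")
  expect_error(fit_cox(six_patient_fixture(), character(0)), "at least one")
  expect_error(fit_cox(six_patient_fixture(), "nope"), "missing column")
})

test_that("per-SD hazard ratios are invariant to affine rescaling", {
  coh <- generate_cohort(cohort_config(n_patients = 800, seed = 14))
  f1 <- fit_cox(coh, "ihc4", per_sd = "ihc4")
  coh$ihc4_rescaled <- 3.7 * coh$ihc4 - 12
  f2 <- fit_cox(coh, "ihc4_rescaled", per_sd = "ihc4_rescaled")
  expect_equal(f1$terms$hr, f2$terms$hr, tolerance = 1e-9)
  expect_equal(f1$lr_chisq, f2$lr_chisq, tolerance = 1e-9)
})

test_that("compare_nested computes delta LR chi-square correctly", {
  coh <- generate_cohort(cohort_config(n_patients = 800, seed = 15))
  coh <- truncate_at_10y(coh)
  full <- fit_cox(coh, c("ihc4", "predict_score", "age_years"),
                  per_sd = c("ihc4", "predict_score"))
  red <- fit_cox(coh, c("predict_score", "age_years"), per_sd = "predict_score")
  cmp <- compare_nested(full, red)
  expect_equal(cmp$delta_lr_chisq, 2 * (full$loglik - red$loglik))
  expect_equal(cmp$df, 1L)
  expect_gte(cmp$delta_lr_chisq, 0)
  # model against itself: delta 0, p 1
  self <- compare_nested(full, full)
  expect_equal(self$delta_lr_chisq, 0)
  expect_equal(self$p_value, 1)
  # non-nested and different-sample guards
  other <- fit_cox(coh, "c_score", per_sd = "c_score")
  expect_error(compare_nested(red, full), "not nested")
  expect_error(compare_nested(fit_cox(coh[1:700, ], "ihc4", per_sd = "ihc4"),
                              fit_cox(coh, "ihc4", per_sd = "ihc4")),
               "different samples")
})

test_that("a pure-noise covariate's delta LR is chi-square(1)-like", {
  deltas <- vapply(1:300, function(s) {
    withr::with_seed(s + 900, {
      d <- data.frame(time_years = rexp(150, 0.1), event = rbinom(150, 1, 0.7),
                      x = rnorm(150), noise = rnorm(150))
    })
    full <- fit_cox(d, c("x", "noise"))
    red <- fit_cox(d, "x")
    compare_nested(full, red)$delta_lr_chisq
  }, numeric(1))
  expect_equal(mean(deltas), 1, tolerance = 0.2)
  expect_lt(abs(mean(deltas > qchisq(0.95, 1)) - 0.05), 0.035)
})

test_that("km_logrank handles trivial and stratified cases", {
  withr::with_seed(81, base <- data.frame(time_years = rexp(60, 0.2) + 0.01,
                                          event = rbinom(60, 1, 0.8)))
  dup <- rbind(cbind(base, g = "a"), cbind(base, g = "b"))
  km <- km_logrank(dup, "g")
  expect_lt(km$logrank_chisq, 1e-9)
  expect_equal(km$p, 1, tolerance = 1e-6)
  # no censoring: KM equals the empirical survival function
  nc <- base; nc$event <- 1L; nc <- rbind(cbind(nc, g = "a"), cbind(nc, g = "b"))
  km <- km_logrank(nc, "g")
  ca <- km$curves[km$curves$group == "a", ]
  emp <- vapply(ca$time, function(t) mean(base$time_years > t), numeric(1))
  expect_equal(ca$surv, emp, tolerance = 1e-9)
  # survival estimates are non-increasing from 1 within each group
  expect_true(all(tapply(km$curves$surv, km$curves$group,
                         function(s) all(diff(s) <= 0) && s[1] <= 1)))
  expect_error(km_logrank(dup, "time_years2"), "unknown grouping")
  one <- cbind(base, g = "a")
  expect_error(km_logrank(one, "g"), "two groups")
  # stratified call returns one result per stratum
  dup$stratum <- rep(c("s1", "s2"), 60)
  res <- km_logrank(dup, "g", strata = "stratum")
  expect_named(res, c("s1", "s2"))
  expect_s3_class(res$s1, "km_result")
})

test_that("log-rank detects a strong group effect", {
  # scaled-down power check: HR 2 between groups at n = 1000
  hits <- vapply(1:50, function(s) {
    withr::with_seed(s + 300, {
      g <- rep(0:1, 500)
      t_ev <- rexp(1000, 0.05 * 2^g)
      cens <- runif(1000, 4, 10)
      d <- data.frame(time_years = pmin(t_ev, cens),
                      event = as.integer(t_ev <= cens),
                      g = factor(g))
    })
    km_logrank(d, "g")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ph_check is deterministic and flags decaying effects", {
  coh <- generate_cohort(cohort_config(n_patients = 700, seed = 17))
  p1 <- ph_check(coh, "ihc4", per_sd = "ihc4")
  p2 <- ph_check(coh, "ihc4", per_sd = "ihc4")
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # strong non-PH alternative: group effect that reverses over time
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s + 70, {
      x <- rep(0:1, 1000)
      sh <- ifelse(x == 1, 0.6, 1.8)          # crossing hazards
      t_ev <- rweibull(2000, shape = sh, scale = 8)
      cens <- runif(2000, 5, 10)
      d <- data.frame(time_years = pmin(t_ev, cens),
                      event = as.integer(t_ev <= cens), x = x)
    })
    ph_check(d, "x")[[1]] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("heterogeneity_test is a valid 1-df interaction LR test", {
  coh <- generate_cohort(cohort_config(n_patients = 2000, seed = 19))
  coh$subtype <- as.character(classify_cohort(coh))
  coh <- truncate_at_10y(apply_exclusions(coh))
  coh$predict_score_z <- as.numeric(standardize_per_sd(coh$predict_score))
  het <- heterogeneity_test(coh, "ihc4", "subtype",
                            adjust = c("predict_score_z", "age_years"))
  expect_gte(het$delta_lr_chisq, 0)
  expect_true(het$p_value >= 0 && het$p_value <= 1)
  expect_equal(het$df, 1L)
  only_a <- coh[coh$subtype == "A_LIKE", ]
  expect_error(heterogeneity_test(only_a, "ihc4", "subtype"), "both subtypes")
})

test_that("heterogeneity_test keeps its nominal size under equal effects", {
  rejections <- vapply(1:60, function(s) {
    coh <- generate_cohort(cohort_config(n_patients = 1200, seed = 2200 + s))
    coh$subtype <- as.character(classify_cohort(coh))
    coh <- truncate_at_10y(coh)
    het <- heterogeneity_test(coh, "ihc4", "subtype", adjust = "age_years")
    het$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.08)
})
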