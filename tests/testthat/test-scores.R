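test_that("aggregate_cores averages markers over measured cores", {
  one <- data.frame(er_pct = 80, pr_pct = 60, ki67_pct = 10, her2_herceptest = 1)
  expect_equal(aggregate_cores(one), one)

  two <- data.frame(er_pct = c(60, 80), pr_pct = c(50, 50),
                    ki67_pct = c(5, 5), her2_herceptest = c(0, 0))
  expect_equal(aggregate_cores(two)$er_pct, 70)

  three <- data.frame(er_pct = c(50, 50, 50), pr_pct = c(40, 40, 40),
                      ki67_pct = c(0, 9, 27), her2_herceptest = c(0, 3, 3))
  agg <- aggregate_cores(three)
  expect_equal(agg$ki67_pct, 12)
  expect_equal(agg$her2_herceptest, 2.0)

  # marker missing on some cores: mean over the measured ones only
  part <- data.frame(er_pct = c(NA, 30), pr_pct = c(20, NA),
                     ki67_pct = c(10, 20), her2_herceptest = c(1, NA))
  agg <- aggregate_cores(part)
  expect_equal(agg$er_pct, 30)
  expect_equal(agg$pr_pct, 20)
  expect_equal(agg$her2_herceptest, 1)

  # marker missing on all cores is flagged missing, not an error
  allna <- data.frame(er_pct = c(60, 80), pr_pct = c(NA, NA),
                      ki67_pct = c(5, 5), her2_herceptest = c(0, 0))
  expect_true(is.na(aggregate_cores(allna)$pr_pct))

  expect_error(aggregate_cores(data.frame()), "non-empty")
  expect_error(aggregate_cores(
    data.frame(er_pct = NA, pr_pct = NA, ki67_pct = NA,
               her2_herceptest = NA)), "at least one marker")
})

test_that("aggregate_cores groups by patient_id", {
  cores <- data.frame(patient_id = c("a", "a", "b"),
                      er_pct = c(10, 30, 90), pr_pct = c(0, 0, 50),
                      ki67_pct = c(1, 3, 5), her2_herceptest = c(0, 0, 3))
  agg <- aggregate_cores(cores)
  expect_equal(nrow(agg), 2L)
  expect_equal(agg$er_pct[agg$patient_id == "a"], 20)
  expect_equal(agg$er_pct[agg$patient_id == "b"], 90)
})

test_that("compute_ihc4 matches its analytic spot values", {
  expect_equal(compute_ihc4(0, 0, 0, 0), 0)
  expect_equal(compute_ihc4(100, 100, 0, 0), 94.7 * -1.79)
  # cohort-median profile, frozen from the hand oracle
  expect_equal(compute_ihc4(62, 57, 9, 0), oracle_ihc4(62, 57, 9, 0),
               tolerance = 1e-12)
  expect_equal(compute_ihc4(62, 57, 9, 0), 1.1654, tolerance = 1e-3)
})

test_that("compute_ihc4 honours unit and HER2-coding options", {
  frac <- score_options(ki67_unit = "fraction")
  expect_equal(compute_ihc4(50, 50, 20, 1, frac),
               oracle_ihc4(50, 50, 20, 1, ki67_percent = FALSE),
               tolerance = 1e-12)
  bin <- score_options(her2_coding = "clinical_binary")
  expect_equal(compute_ihc4(50, 50, 20, 1, bin), oracle_ihc4(50, 50, 20, 1))
  # binary coding rejects an ordinal-scale input
  expect_error(compute_ihc4(50, 50, 20, 3, bin), "out of range")
})

test_that("compute_ihc4 errors name the offending component", {
  expect_error(compute_ihc4(NA, 50, 10, 0), "er_pct")
  expect_error(compute_ihc4(50, 50, NA, 0), "ki67_pct")
  expect_error(compute_ihc4(50, 50, -2, 0), "ki67")
})

test_that("IHC4 is strictly monotone in each marker", {
  withr::with_seed(42, {
    for (i in 1:50) {
      er <- runif(1, 0, 99); pr <- runif(1, 0, 99)
      ki <- runif(1, 0, 99); h2 <- runif(1, 0, 2.9)
      base <- compute_ihc4(er, pr, ki, h2)
      expect_lt(compute_ihc4(er + 1, pr, ki, h2), base)
      expect_lt(compute_ihc4(er, pr + 1, ki, h2), base)
      expect_gt(compute_ihc4(er, pr, ki + 1, h2), base)
      expect_gt(compute_ihc4(er, pr, ki, h2 + 0.1), base)
    }
  })
})

test_that("compute_c_score matches the hand oracle and its spot values", {
  expect_equal(compute_c_score(50, 8, 1, 0), 0)        # full reference
  expect_equal(compute_c_score(70, 15, 2, 2), 156.821) # 0.417+0.930*0.497+0.559+0.130
  expect_equal(compute_c_score(50, 35, 3, 5), 437.4)   # 1.566+1.838+0.970
  # age boundary is closed at 65
  expect_equal(compute_c_score(65, 8, 1, 0), 13)
  wb <- score_options(c_score_bracket_convention = "whole_bracket")
  expect_equal(compute_c_score(70, 15, 2, 2, wb),
               oracle_c_score(70, 15, 2, 2, whole_bracket = TRUE))
  expect_error(compute_c_score(50, -3, 2, 0), "positive")
  expect_error(compute_c_score(50, 10, 2, -1), "non-negative")
})

test_that("C-score is non-negative and zero only at full reference", {
  inputs <- random_clinical_inputs(500, seed = 9)
  s <- compute_c_score(inputs$age, inputs$size, inputs$grade, inputs$nodes)
  expect_true(all(s >= 0))
  ref <- inputs$age < 65 & inputs$size <= 10 & inputs$grade == 1 & inputs$nodes == 0
  expect_equal(s == 0, ref)
})

test_that("compute_predict_score matches the hand oracle and spot values", {
  expect_equal(compute_predict_score(50, 20, 2, 0), 0.68622, tolerance = 1e-4)
  expect_equal(compute_predict_score(65, 15, 1, 2), 0.62211, tolerance = 1e-4)
  expect_equal(compute_predict_score(50, 20, 2, 0),
               oracle_predict(50, 20, 2, 0), tolerance = 1e-12)
  # the grade term is linear: grade 3 minus grade 2 is exactly 0.7467
  expect_equal(compute_predict_score(44, 33, 3, 2) -
                 compute_predict_score(44, 33, 2, 2), 0.7467)
  expect_error(compute_predict_score(0, 20, 2, 0), "age")
  expect_error(compute_predict_score(50, 0, 2, 0), "positive")
})

test_that("subtype classification follows the published binary rules", {
  expect_equal(as.character(classify_subtype(TRUE, TRUE, FALSE, 10)), "A_LIKE")
  expect_equal(as.character(classify_subtype(TRUE, FALSE, TRUE, 5)), "B_LIKE")
  expect_equal(as.character(classify_subtype(TRUE, FALSE, FALSE, 5)), "UNCLASSIFIED")
  # KI67 boundary: 12 is low proliferating, above 12 is not
  expect_equal(as.character(classify_subtype(TRUE, TRUE, FALSE, 12)), "A_LIKE")
  expect_equal(as.character(classify_subtype(TRUE, TRUE, FALSE, 12.1)), "B_LIKE")
  expect_error(classify_subtype(FALSE, FALSE, FALSE, 5), "not luminal")
  expect_equal(as.character(classify_subtype(FALSE, FALSE, TRUE, 5,
                                             on_nonluminal = "label")),
               "NON_LUMINAL")
})

test_that("positivity thresholds use the published open/closed conventions", {
  # 10% convention is exclusive (Allred > 2 means > 10% cells)
  expect_false(marker_positive(10, threshold = 10))
  expect_true(marker_positive(10.5, threshold = 10))
  # 1% convention is inclusive
  expect_true(marker_positive(1, threshold = 1))
  expect_false(marker_positive(0.5, threshold = 1))
  # clinical record status wins when present
  expect_true(marker_positive(c(0, 50), clinical = c(1, NA))[1])
})

test_that("relaxing the ER/PR threshold never moves B-like to A-like", {
  withr::with_seed(31, {
    n <- 400
    coh <- data.frame(er_pct = runif(n, 0, 100), pr_pct = runif(n, 0, 100),
                      ki67_pct = runif(n, 0, 40),
                      her2_herceptest = sample(c(0, 1, 2, 3), n, TRUE))
  })
  l10 <- classify_cohort(coh, score_options(), on_nonluminal = "label")
  l1 <- classify_cohort(coh, score_options(er_pr_positivity_threshold = 1),
                        on_nonluminal = "label")
  expect_false(any(l10 == "B_LIKE" & l1 == "A_LIKE"))
})

test_that("standardize_per_sd yields mean 0, sample SD 1", {
  z <- standardize_per_sd(c(0, 0, 10, 10))
  expect_equal(as.numeric(z), c(-0.8660254, -0.8660254, 0.8660254, 0.8660254),
               tolerance = 1e-7)
  withr::with_seed(5, x <- rlnorm(200))
  z <- standardize_per_sd(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_error(standardize_per_sd(rep(3, 10)), "zero-variance")
})

test_that("dichotomize_mean_plus_sd uses the mean + 1 sample SD cut", {
  d <- dichotomize_mean_plus_sd(c(0, 0, 0, 10))
  expect_equal(d$threshold, 7.5)
  expect_equal(d$high, c(FALSE, FALSE, FALSE, TRUE))
  # one extreme outlier: exactly that observation is high
  d <- dichotomize_mean_plus_sd(c(rep(1, 20), 200))
  expect_equal(sum(d$high), 1L)
  # standard normal: high fraction approaches 1 - Phi(1) = 0.1587
  withr::with_seed(8, x <- rnorm(1e5))
  expect_equal(mean(dichotomize_mean_plus_sd(x)$high), pnorm(-1),
               tolerance = 0.01)
  expect_error(dichotomize_mean_plus_sd(c(2, 2)), "zero-variance")
})

test_that("assign_quartiles bins at type-7 percentiles, ties to the lower bin", {
  expect_equal(as.character(assign_quartiles(1:8)),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  # a data value exactly on a break goes to the lower bin
  expect_equal(as.character(assign_quartiles(1:5)),
               c("Q1", "Q1", "Q2", "Q3", "Q4"))
  # rank invariance under strictly monotone transforms
  withr::with_seed(13, x <- rnorm(101))
  expect_equal(assign_quartiles(x), assign_quartiles(exp(x)))
  expect_error(assign_quartiles(c(1, 1, 2, 3)), "four distinct")
  levs <- levels(assign_quartiles(1:8))
  expect_equal(levs, c("Q1", "Q2", "Q3", "Q4"))
})
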