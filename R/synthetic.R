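# Synthetic cohort generator.  Emulates the marker distributions, clinical
# margins and event frequency of a two-study European luminal breast cancer
# cohort (overall n = 2498, 316 breast-cancer deaths over ~7-year median
# follow-up) so that every downstream analysis stage can be exercised without
# patient-level data.  The survival mechanism is a Weibull proportional-
# hazards model — an invented generative model chosen for closed-form
# inversion and exact PH compliance, not something estimated from the study.

#' Solve scaled-beta parameters from a median/SD target
#'
#' Marker percentages are modelled as 100 times a beta variate.  The beta
#' family is chosen because it is bounded on \[0, 1\] and covers both the
#' U-shaped ER/PR distributions (mass piled near 0 and 100) and the
#' right-skewed KI67 distribution.  Shape parameters are found numerically so
#' the distribution's median and standard deviation match the targets.
#'
#' @param median_frac,sd_frac Target median and SD on the \[0, 1\] scale.
#' @return Named vector `c(shape1, shape2)`.
#' @export
fit_beta_median_sd <- function(median_frac, sd_frac) {
  if (median_frac <= 0 || median_frac >= 1 || sd_frac <= 0 || sd_frac >= 0.5) {
    abort("infeasible beta target: median must be in (0,1), sd in (0, 0.5)")
  }
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    v <- a * b / ((a + b)^2 * (a + b + 1))
    (stats::qbeta(0.5, a, b) - median_frac)^2 + (sqrt(v) - sd_frac)^2
  }
  fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value > 1e-6) {
    abort("infeasible distribution target: no beta distribution attains ",
          "median ", median_frac, " with sd ", sd_frac)
  }
  c(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]))
}

# Clinical category margins.  The `overall` preset carries the published
# two-study frequencies; `pbcs` and `search` the per-study columns.  The
# split of node-positive disease into 1-3 vs 4+ nodes is not published and
# is fixed at 72/28 of the positive fraction.
preset_margins <- function(preset = c("overall", "pbcs", "search")) {
  preset <- match.arg(preset)
  m <- switch(preset,
    overall = list(age = c(0.016, 0.322, 0.537, 0.124),
                   grade = c(0.261, 0.557, 0.182),
                   size = c(0.655, 0.321, 0.024),
                   node_negative = 0.609,
                   endocrine_therapy = 0.804,
                   chemotherapy = 0.07,
                   study_pbcs = 558 / 2498),
    pbcs = list(age = c(0.005, 0.265, 0.487, 0.242),
                grade = c(0.265, 0.613, 0.122),
                size = c(0.593, 0.376, 0.030),
                node_negative = 0.560,
                endocrine_therapy = 0.644,
                chemotherapy = 0.07,
                study_pbcs = 1),
    search = list(age = c(0.020, 0.338, 0.552, 0.091),
                  grade = c(0.260, 0.538, 0.202),
                  size = c(0.674, 0.304, 0.022),
                  node_negative = 0.625,
                  endocrine_therapy = 0.862,
                  chemotherapy = 0.07,
                  study_pbcs = 0))
  m$age <- m$age / sum(m$age)
  m$grade <- m$grade / sum(m$grade)
  m$size <- m$size / sum(m$size)
  m$node_pos_13 <- 0.72
  m
}

#' Configure a synthetic cohort
#'
#' The defaults encode the published cohort: ER/PR/KI67 image-analysis score
#' medians (SDs) of 62% (34), 57% (38) and 9% (11); 9% HER2-positive
#' prevalence; and the clinical category margins of the chosen preset
#' (`overall`, `pbcs` or `search`).
#'
#' @param n_patients Number of patients (>= 1).
#' @param preset Margin preset: `"overall"` (default), `"pbcs"` or `"search"`.
#' @param marker_targets Named list of `c(median, sd)` pairs on the percent
#'   scale for `er`, `pr`, `ki67`.
#' @param her2_pos_prevalence Probability of HER2 3+ disease (default 0.09).
#' @param her2_negative_split Probabilities of Herceptest 0/1+/2+ among
#'   HER2-negative patients (unpublished; fixed documented constant).
#' @param clinical_margins Optional margin list overriding the preset (same
#'   shape as the preset list).
#' @param seed Integer seed making the cohort fully reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2498,
                          preset = "overall",
                          marker_targets = list(er = c(62, 34),
                                                pr = c(57, 38),
                                                ki67 = c(9, 11)),
                          her2_pos_prevalence = 0.09,
                          her2_negative_split = c(0.5, 0.3, 0.2),
                          clinical_margins = NULL,
                          seed = 1L) {
  if (n_patients < 1) abort("n_patients must be >= 1")
  if (her2_pos_prevalence < 0 || her2_pos_prevalence > 1) {
    abort("her2_pos_prevalence must be a probability")
  }
  if (abs(sum(her2_negative_split) - 1) > 1e-8) {
    abort("her2_negative_split must sum to 1")
  }
  margins <- if (is.null(clinical_margins)) preset_margins(preset) else clinical_margins
  for (nm in c("age", "grade", "size")) {
    if (abs(sum(margins[[nm]]) - 1) > 1e-8) {
      abort("clinical margin '", nm, "' must sum to 1")
    }
  }
  stopifnot(all(vapply(marker_targets, length, 1L) == 2L))
  # solve the beta shapes once, at configuration time
  shapes <- lapply(marker_targets, function(t) {
    fit_beta_median_sd(t[1] / 100, t[2] / 100)
  })
  structure(list(n_patients = as.integer(n_patients), preset = preset,
                 marker_targets = marker_targets, beta_shapes = shapes,
                 her2_pos_prevalence = her2_pos_prevalence,
                 her2_negative_split = her2_negative_split,
                 clinical_margins = margins, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Configure the synthetic survival mechanism
#'
#' Event times follow a Weibull proportional-hazards model,
#' \eqn{S(t \mid z) = \exp\{-(t/\lambda)^k e^{\beta z}\}}, where `z` is the
#' standardised prognostic predictor and \eqn{\beta} the per-SD log hazard
#' ratio.  Follow-up ends at the earlier of an entry-dependent censoring time
#' (uniform on \[`admin_censor_years - followup_window_years`,
#' `admin_censor_years`\], giving a ~7-year median follow-up with the
#' defaults) and the 10-year administrative horizon.  Unless `scale` is
#' supplied, the Weibull scale is calibrated so the expected event fraction
#' matches `target_event_fraction` (default 316/2498).
#'
#' @param shape Weibull shape (> 0; default 1.2, a mildly increasing hazard).
#' @param scale Weibull scale in years, or `NULL` to calibrate.
#' @param log_hr_per_sd Per-SD log hazard ratio of the latent predictor
#'   (default `log(1.32)`, the published univariable IHC4 effect size).
#' @param admin_censor_years Administrative censoring horizon (default 10).
#' @param followup_window_years Width of the uniform entry window (default 6).
#' @param target_event_fraction Calibration target for the realised event
#'   fraction (default 316/2498).
#' @return An object of class `hazard_config`.
#' @export
hazard_config <- function(shape = 1.2, scale = NULL,
                          log_hr_per_sd = log(1.32),
                          admin_censor_years = 10,
                          followup_window_years = 6,
                          target_event_fraction = 316 / 2498) {
  if (shape <= 0) abort("Weibull shape must be positive")
  if (!is.null(scale) && scale <= 0) abort("Weibull scale must be positive")
  if (admin_censor_years <= 0) abort("admin_censor_years must be positive")
  if (followup_window_years < 0 || followup_window_years > admin_censor_years) {
    abort("followup_window_years must be in [0, admin_censor_years]")
  }
  if (target_event_fraction <= 0 || target_event_fraction >= 1) {
    abort("target_event_fraction must be in (0, 1)")
  }
  structure(list(shape = shape, scale = scale, log_hr_per_sd = log_hr_per_sd,
                 admin_censor_years = admin_censor_years,
                 followup_window_years = followup_window_years,
                 target_event_fraction = target_event_fraction),
            class = "hazard_config")
}

#' Generate marker columns for a synthetic cohort
#'
#' ER, PR and KI67 percentages are drawn from the configured scaled-beta
#' distributions; the Herceptest ordinal is 3 with probability
#' `her2_pos_prevalence` and otherwise 0/1+/2+ per the negative split.
#' Clinical-record statuses are derived from the percentages at the 10%
#' (exclusive) convention and HER2 3+.  Because the emulated cohort is
#' luminal by inclusion criterion, rows with neither receptor positive are
#' redrawn until every patient is ER+ and/or PR+.
#'
#' @param cfg A [cohort_config()].
#' @param seed Optional seed override (defaults to stage 1 child of
#'   `cfg$seed`).
#' @return Data frame of marker columns, one row per patient.
#' @export
generate_markers <- function(cfg, seed = child_seed(cfg$seed, 1L)) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_patients
  withr::with_seed(seed, {
    sh <- cfg$beta_shapes
    er <- 100 * stats::rbeta(n, sh$er[1], sh$er[2])
    pr <- 100 * stats::rbeta(n, sh$pr[1], sh$pr[2])
    ki67 <- 100 * stats::rbeta(n, sh$ki67[1], sh$ki67[2])
    # luminal inclusion: redraw ER/PR jointly for non-luminal rows
    for (it in 1:100) {
      bad <- which(er <= 10 & pr <= 10)
      if (!length(bad)) break
      er[bad] <- 100 * stats::rbeta(length(bad), sh$er[1], sh$er[2])
      pr[bad] <- 100 * stats::rbeta(length(bad), sh$pr[1], sh$pr[2])
    }
    if (any(er <= 10 & pr <= 10)) abort("failed to enforce luminal inclusion")
    her2_pos <- stats::rbinom(n, 1L, cfg$her2_pos_prevalence) == 1L
    her2 <- ifelse(her2_pos, 3,
                   sample(c(0, 1, 2), n, replace = TRUE,
                          prob = cfg$her2_negative_split))
    data.frame(er_pct = er, pr_pct = pr, ki67_pct = ki67,
               her2_herceptest = her2,
               er_clinical_pos = as.integer(er > 10),
               pr_clinical_pos = as.integer(pr > 10),
               her2_clinical_pos = as.integer(her2 == 3))
  })
}

#' Generate clinical-factor columns for a synthetic cohort
#'
#' Draws each categorical factor from the configured margins, then samples a
#' continuous value uniformly within the drawn category: age brackets
#' (<35, 35-50, 50-65, >65, capped at 78), size brackets (<2 cm, 2-5 cm,
#' >5 cm, in mm), nodal count (0; 1-3; 4 plus a Poisson(3) excess).
#'
#' @inheritParams generate_markers
#' @return Data frame of clinical columns, one row per patient.
#' @export
generate_clinical <- function(cfg, seed = child_seed(cfg$seed, 2L)) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_patients
  m <- cfg$clinical_margins
  withr::with_seed(seed, {
    age_cat <- sample.int(4L, n, replace = TRUE, prob = m$age)
    age_lo <- c(25, 35, 50, 65)[age_cat]
    age_hi <- c(35, 50, 65, 78)[age_cat]
    age <- stats::runif(n, age_lo, age_hi)
    grade <- sample.int(3L, n, replace = TRUE, prob = m$grade)
    size_cat <- sample.int(3L, n, replace = TRUE, prob = m$size)
    size <- stats::runif(n, c(3, 20, 50)[size_cat], c(20, 50, 80)[size_cat])
    node_pos <- stats::runif(n) > m$node_negative
    n13 <- node_pos & stats::runif(n) < m$node_pos_13
    nodes <- integer(n)
    nodes[n13] <- sample(1:3, sum(n13), replace = TRUE, prob = c(0.5, 0.3, 0.2))
    n4 <- node_pos & !n13
    nodes[n4] <- 4L + stats::rpois(sum(n4), 3)
    data.frame(age_years = age, tumor_size_mm = size, grade = grade,
               positive_nodes = nodes,
               endocrine_therapy = stats::rbinom(n, 1L, m$endocrine_therapy),
               chemotherapy = stats::rbinom(n, 1L, m$chemotherapy),
               study = ifelse(stats::runif(n) < m$study_pbcs, "PBCS", "SEARCH"))
  })
}

# Calibrate the Weibull scale so the expected event fraction over the
# realised linear predictors and censoring times hits the target.  The
# per-subject event probability given (lp, C) is 1 - exp(-(C/s)^k e^lp),
# which is averaged analytically over the sample — no inner simulation.
calibrate_scale <- function(lp, censor, hz) {
  f <- function(log_s) {
    s <- exp(log_s)
    mean(1 - exp(-(censor / s)^hz$shape * exp(lp))) - hz$target_event_fraction
  }
  exp(stats::uniroot(f, c(-3, 12), tol = 1e-10)$root)
}

#' Simulate breast cancer-specific survival under Weibull PH
#'
#' @param predictor Numeric prognostic predictor, one value per patient;
#'   standardised internally (when its spread is nonzero) so that
#'   `hz$log_hr_per_sd` is the per-SD log hazard ratio.
#' @param hz A [hazard_config()].
#' @param seed Integer seed.
#' @return Data frame with `time_years` (0 < t <= admin horizon) and `event`
#'   (1 = breast-cancer death).  The latent linear predictor and the
#'   calibrated Weibull scale are attached as attributes `lp` and `scale`.
#' @export
simulate_survival <- function(predictor, hz = hazard_config(), seed = 1L) {
  stopifnot(inherits(hz, "hazard_config"))
  if (!all(is.finite(predictor))) abort("predictor contains non-finite values")
  n <- length(predictor)
  z <- if (n >= 2L && stats::sd(predictor) > 0) {
    as.numeric(standardize_per_sd(predictor))
  } else {
    rep(0, n)
  }
  lp <- hz$log_hr_per_sd * z
  withr::with_seed(seed, {
    censor <- stats::runif(n, hz$admin_censor_years - hz$followup_window_years,
                           hz$admin_censor_years)
    s <- if (is.null(hz$scale)) calibrate_scale(lp, censor, hz) else hz$scale
    u <- stats::runif(n)
    t_event <- s * (-log(u) * exp(-lp))^(1 / hz$shape)
    out <- data.frame(time_years = pmin(t_event, censor),
                      event = as.integer(t_event <= censor))
    attr(out, "lp") <- lp
    attr(out, "scale") <- s
    out
  })
}

#' Generate a complete synthetic cohort
#'
#' Composes the marker, clinical and survival generators, computes the
#' prognostic scores with the supplied conventions, and drives the hazard
#' with the chosen predictor (default the IHC4 score, matching the scenario
#' in which the quantitative score carries the true prognostic signal).
#' Fully deterministic given `cfg$seed`: the three stages draw from
#' independent child seeds.
#'
#' @param cfg A [cohort_config()].
#' @param hz A [hazard_config()].
#' @param predictor Name of the score column driving the hazard (`"ihc4"`,
#'   `"c_score"`, or `"predict_score"`), or a numeric vector of length
#'   `cfg$n_patients`.
#' @param opts [score_options()] used for score computation.
#' @return Patient-level data frame (one row per patient) with marker,
#'   clinical, score, latent-predictor (`lp_true`) and survival columns.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 200, seed = 7))
#' head(coh)
generate_cohort <- function(cfg = cohort_config(), hz = hazard_config(),
                            predictor = "ihc4", opts = score_options()) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(hz, "hazard_config"))
  mk <- generate_markers(cfg)
  cl <- generate_clinical(cfg)
  coh <- cbind(patient_id = sprintf("P%05d", seq_len(cfg$n_patients)), mk, cl)
  her2_in <- if (opts$her2_coding == "clinical_binary") coh$her2_clinical_pos else coh$her2_herceptest
  coh$ihc4 <- compute_ihc4(coh$er_pct, coh$pr_pct, coh$ki67_pct, her2_in, opts)
  coh$c_score <- compute_c_score(coh$age_years, coh$tumor_size_mm,
                                 coh$grade, coh$positive_nodes, opts)
  coh$predict_score <- compute_predict_score(coh$age_years, coh$tumor_size_mm,
                                             coh$grade, coh$positive_nodes)
  pred <- if (is.character(predictor)) {
    if (!predictor %in% names(coh)) abort("unknown predictor column '", predictor, "'")
    coh[[predictor]]
  } else {
    if (length(predictor) != nrow(coh)) abort("predictor length mismatch")
    predictor
  }
  sv <- simulate_survival(pred, hz, seed = child_seed(cfg$seed, 3L))
  coh$lp_true <- attr(sv, "lp")
  coh$time_years <- sv$time_years
  coh$event <- sv$event
  attr(coh, "weibull_scale") <- attr(sv, "scale")
  coh
}
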