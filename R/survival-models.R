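# Survival model fitting and comparison.  Cox partial-likelihood machinery is
# delegated to the survival package (Efron ties by default); this module owns
# the analysis conventions: per-SD standardisation of continuous scores,
# LR-chi-square bookkeeping against the intercept-only null, nested-model
# deltas, subtype-heterogeneity interaction tests and the ln(time)
# time-varying-covariate proportionality check.

#' Apply the survival-analysis exclusions
#'
#' Removes chemotherapy recipients (their small number precludes stratified
#' analysis, so they are excluded as in the source analysis convention) and
#' rows with missing values on the requested model covariates (complete-case
#' analysis).  Exclusion counts are attached as attribute `exclusions`.
#'
#' @param cohort Patient-level data frame with a `chemotherapy` flag.
#' @param required Character vector of columns that must be non-missing.
#' @return The filtered cohort, with attribute `exclusions` = named counts
#'   `c(input, chemotherapy, incomplete, analyzed)`.
#' @export
apply_exclusions <- function(cohort, required = character(0)) {
  if (is.null(cohort$chemotherapy)) abort("cohort lacks a chemotherapy flag")
  n0 <- nrow(cohort)
  keep <- is.na(cohort$chemotherapy) | cohort$chemotherapy == 0
  n_chemo <- sum(!keep)
  out <- cohort[keep, , drop = FALSE]
  n_incomplete <- 0L
  if (length(required)) {
    missing_cols <- setdiff(required, names(out))
    if (length(missing_cols)) abort("missing covariate column(s): ",
                                    paste(missing_cols, collapse = ", "))
    cc <- stats::complete.cases(out[required])
    n_incomplete <- sum(!cc)
    out <- out[cc, , drop = FALSE]
  }
  if (nrow(out) == 0L) abort("exclusions removed every patient")
  attr(out, "exclusions") <- c(input = n0, chemotherapy = n_chemo,
                               incomplete = n_incomplete, analyzed = nrow(out))
  out
}

#' Administratively truncate follow-up at a fixed horizon
#'
#' Events and censorings beyond the horizon (default 10 years) are recoded as
#' censored at the horizon, so all analyses address 10-year breast
#' cancer-specific survival.
#'
#' @param cohort Data frame with `time_years` and `event` columns.
#' @param horizon Truncation horizon in years (default 10).
#' @return The cohort with truncated `time_years`/`event`.
#' @export
truncate_at_10y <- function(cohort, horizon = 10) {
  if (any(cohort$time_years <= 0)) abort("follow-up times must be positive")
  late <- cohort$time_years > horizon
  cohort$event[late] <- 0L
  cohort$time_years[late] <- horizon
  cohort
}

#' Fit a Cox proportional hazards model
#'
#' Maximises the Cox partial likelihood (Efron tie handling by default) for
#' the requested covariates.  Covariates named in `per_sd` are divided by
#' their sample standard deviation (n-1 denominator, computed on the analysis
#' rows) before fitting, so their hazard ratios are per 1 SD of the score.
#'
#' @param cohort Data frame with `time_years`, `event` and the covariates.
#' @param covariates Character vector of covariate columns (factors allowed).
#' @param per_sd Subset of `covariates` to standardise to per-SD units.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`: a list with a tidy `terms` table
#'   (term, coef, hr, ci_low, ci_high, p), `loglik`, `null_loglik`,
#'   `lr_chisq`, `df`, `lr_p`, `n`, `n_events`, the per-SD scale factors,
#'   and the underlying `survival::coxph` fit.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 300, seed = 3))
#' fit_cox(coh, "ihc4", per_sd = "ihc4")
fit_cox <- function(cohort, covariates, per_sd = character(0),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!length(covariates)) abort("at least one covariate is required")
  missing_cols <- setdiff(c("time_years", "event", covariates), names(cohort))
  if (length(missing_cols)) abort("missing column(s): ",
                                  paste(missing_cols, collapse = ", "))
  if (!all(per_sd %in% covariates)) abort("per_sd must be a subset of covariates")
  dat <- cohort[c("time_years", "event", covariates)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (sum(dat$event) < 1) abort("no events in the analysis data")
  sds <- numeric(0)
  for (v in per_sd) {
    s <- stats::sd(dat[[v]])
    if (!is.finite(s) || s == 0) abort("covariate '", v, "' has zero variance")
    dat[[v]] <- dat[[v]] / s
    sds[v] <- s
  }
  for (v in covariates) {
    x <- dat[[v]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      abort("covariate '", v, "' is constant: no information")
    }
    if (is.character(x)) dat[[v]] <- factor(x)
    if (is.factor(x)) dat[[v]] <- droplevels(x)
  }
  fml <- stats::as.formula(paste("survival::Surv(time_years, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (anyNA(stats::coef(fit))) {
    abort("Cox fit failed: collinear or inestimable covariate(s) [",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "), "]")
  }
  sm <- summary(fit)
  terms <- data.frame(term = rownames(sm$coefficients),
                      coef = sm$coefficients[, "coef"],
                      hr = sm$conf.int[, "exp(coef)"],
                      ci_low = sm$conf.int[, "lower .95"],
                      ci_high = sm$conf.int[, "upper .95"],
                      p = sm$coefficients[, "Pr(>|z|)"],
                      row.names = NULL)
  ll <- fit$loglik[2]
  ll0 <- fit$loglik[1]
  lr <- 2 * (ll - ll0)
  df <- length(stats::coef(fit))
  structure(list(terms = terms, loglik = ll, null_loglik = ll0,
                 lr_chisq = lr, df = df,
                 lr_p = stats::pchisq(lr, df, lower.tail = FALSE),
                 n = fit$n, n_events = fit$nevent,
                 covariates = covariates, per_sd_scale = sds,
                 ties = ties, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- x$terms
  tab$hr <- sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
                    tab$hr, tab$ci_low, tab$ci_high)
  print(tab[c("term", "hr", "p")], row.names = FALSE)
  cat(sprintf("LR chi-square vs null = %.2f on %d df (p = %.3g)\n",
              x$lr_chisq, x$df, x$lr_p))
  invisible(x)
}

#' Compare two nested Cox models by likelihood-ratio chi-square
#'
#' The change in likelihood-ratio chi-square when terms are removed from the
#' full model: `delta = 2 * (loglik_full - loglik_reduced)`, referred to a
#' chi-square with df equal to the difference in the number of estimated
#' coefficients.
#'
#' @param full,reduced `cox_fit` objects fitted to the same rows, with the
#'   reduced model's covariates a subset of the full model's.
#' @return A list with `delta_lr_chisq`, `df` and `p_value`.
#' @export
compare_nested <- function(full, reduced) {
  stopifnot(inherits(full, "cox_fit"), inherits(reduced, "cox_fit"))
  if (!all(reduced$covariates %in% full$covariates)) {
    abort("models are not nested: reduced covariates must be a subset of the full model's")
  }
  if (full$n != reduced$n || full$n_events != reduced$n_events) {
    abort("models were fitted to different samples (n or event count differs)")
  }
  delta <- 2 * (full$loglik - reduced$loglik)
  df <- full$df - reduced$df
  p <- if (df == 0) 1 else stats::pchisq(delta, df, lower.tail = FALSE)
  list(delta_lr_chisq = delta, df = df, p_value = p)
}

#' Kaplan-Meier curves and log-rank test by group
#'
#' Product-limit survival estimates per group with a standard log-rank test
#' across groups; optionally repeated within strata (e.g. node-negative vs
#' node-positive disease).
#'
#' @param cohort Data frame with `time_years`, `event` and the grouping
#'   column.
#' @param group Name of the grouping column (factor or character).
#' @param strata Optional name of a stratification column; results are then
#'   returned per stratum.
#' @return An object of class `km_result`: `curves` (data frame of group,
#'   time, n_risk, n_event, surv, lower, upper), `logrank_chisq`, `df`, `p`,
#'   and `groups`.  With `strata`, a named list of `km_result`s.
#' @export
km_logrank <- function(cohort, group, strata = NULL) {
  if (!group %in% names(cohort)) abort("unknown grouping column '", group, "'")
  if (!is.null(strata)) {
    if (!strata %in% names(cohort)) abort("unknown strata column '", strata, "'")
    parts <- split(cohort, cohort[[strata]], drop = TRUE)
    return(lapply(parts, km_logrank, group = group))
  }
  g <- factor(cohort[[group]])
  counts <- table(g)
  if (length(counts) < 2L) abort("need at least two groups for a log-rank test")
  if (any(counts == 0)) {
    abort("empty group(s): ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  dat <- data.frame(time_years = cohort$time_years, event = cohort$event, g = g)
  sf <- survival::survfit(survival::Surv(time_years, event) ~ g, data = dat,
                          conf.type = "log-log")
  grp <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       lower = sf$lower, upper = sf$upper)
  sd_ <- survival::survdiff(survival::Surv(time_years, event) ~ g, data = dat)
  df <- length(counts) - 1L
  structure(list(curves = curves, logrank_chisq = sd_$chisq, df = df,
                 p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
                 groups = names(counts)),
            class = "km_result")
}

#' @export
#' @importFrom graphics legend lines
plot.km_result <- function(x, main = "Kaplan-Meier survival", xlab = "Years",
                           ylab = "Breast cancer-specific survival", ...) {
  groups <- unique(x$curves$group)
  plot(NULL, xlim = c(0, max(x$curves$time)), ylim = c(0, 1),
       xlab = xlab, ylab = ylab, main = main, ...)
  for (i in seq_along(groups)) {
    cv <- x$curves[x$curves$group == groups[i], ]
    lines(c(0, cv$time), c(1, cv$surv), type = "s", col = i, lwd = 2)
  }
  legend("bottomleft", legend = groups, col = seq_along(groups), lwd = 2,
         bty = "n")
  invisible(x)
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier / log-rank across groups:",
      paste(x$groups, collapse = ", "), "\n")
  cat(sprintf("log-rank chi-square = %.3f on %d df, p = %.3g\n",
              x$logrank_chisq, x$df, x$p))
  invisible(x)
}

#' Proportional-hazards check via time-varying covariates
#'
#' Refits the model with each covariate additionally entered as a
#' `covariate x ln(time)` time-varying interaction; a small interaction
#' p-value signals departure from proportional hazards for that term.  The
#' log transform of time is a conventional choice for this diagnostic.
#'
#' @inheritParams fit_cox
#' @return Named numeric vector of interaction (Wald) p-values, one per
#'   model coefficient.
#' @export
ph_check <- function(cohort, covariates, per_sd = character(0)) {
  dat <- cohort[c("time_years", "event", covariates)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  for (v in per_sd) {
    s <- stats::sd(dat[[v]])
    if (!is.finite(s) || s == 0) abort("covariate '", v, "' has zero variance")
    dat[[v]] <- dat[[v]] / s
  }
  for (v in covariates) if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  fml <- stats::as.formula(paste(
    "survival::Surv(time_years, event) ~",
    paste(covariates, collapse = " + "), "+",
    paste(sprintf("tt(%s)", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat,
                         tt = function(x, t, ...) {
                           if (is.factor(x)) x <- as.numeric(x) - 1
                           x * log(t)
                         })
  sm <- summary(fit)$coefficients
  p <- sm[grepl("^tt\\(", rownames(sm)), "Pr(>|z|)"]
  names(p) <- rownames(sm)[grepl("^tt\\(", rownames(sm))]
  p
}

#' Test heterogeneity of a score's effect across subtypes
#'
#' Likelihood-ratio test of the `score x subtype` interaction added to a
#' model containing the score, the subtype and any adjustment terms: a 1-df
#' chi-square test of whether the per-SD effect of the score differs between
#' luminal A-like and B-like disease.
#'
#' @param cohort Analysis data frame.
#' @param score Name of the continuous score column (standardised per SD
#'   internally).
#' @param subtype Name of the subtype column; only rows with `A_LIKE` or
#'   `B_LIKE` labels are used.
#' @param adjust Character vector of adjustment covariates.
#' @return A list with `p_value`, `delta_lr_chisq`, `df`, and the two fits.
#' @export
heterogeneity_test <- function(cohort, score, subtype, adjust = character(0)) {
  dat <- cohort[cohort[[subtype]] %in% c("A_LIKE", "B_LIKE"), , drop = FALSE]
  dat[[subtype]] <- factor(as.character(dat[[subtype]]),
                           levels = c("A_LIKE", "B_LIKE"))
  ev <- tapply(dat$event, dat[[subtype]], sum)
  if (length(ev) < 2L || any(is.na(ev)) || any(ev == 0)) {
    abort("both subtypes must be represented with events")
  }
  dat[[score]] <- dat[[score]] / stats::sd(dat[[score]])
  base_terms <- c(score, subtype, adjust)
  fml0 <- stats::as.formula(paste("survival::Surv(time_years, event) ~",
                                  paste(base_terms, collapse = " + ")))
  fml1 <- stats::as.formula(paste("survival::Surv(time_years, event) ~",
                                  paste(c(base_terms,
                                          paste0(score, ":", subtype)),
                                        collapse = " + ")))
  f0 <- survival::coxph(fml0, data = dat, ties = "efron")
  f1 <- survival::coxph(fml1, data = dat, ties = "efron")
  delta <- 2 * (f1$loglik[2] - f0$loglik[2])
  list(p_value = stats::pchisq(delta, 1, lower.tail = FALSE),
       delta_lr_chisq = delta, df = 1L, fit_base = f0, fit_interaction = f1)
}
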