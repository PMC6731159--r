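# End-to-end analysis pipeline: cohort -> scores -> subtype -> exclusions ->
# 10-year truncation -> Cox model suite -> KM suite -> report tables.

#' Configure an end-to-end analysis run
#'
#' Exactly one input source must be given: a cohort CSV path, or a synthetic
#' preset (generated at run time from `seed`).
#'
#' @param csv Path to a cohort CSV (patient-level or core-level), or `NULL`.
#' @param preset Synthetic preset name (`"overall"`, `"pbcs"`, `"search"`)
#'   when no CSV is given.
#' @param n_patients Synthetic cohort size (default 2498).
#' @param seed Global seed; fanned out to per-stage child seeds.
#' @param score_opts [score_options()] for scoring and subtype rules.
#' @param hazard [hazard_config()] for synthetic survival generation.
#' @param stratify_by_study Also fit every model within each study
#'   population (default `TRUE`).
#' @param output_dir Directory for report files, or `NULL` to skip writing.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(csv = NULL, preset = NULL, n_patients = 2498,
                            seed = 1L, score_opts = score_options(),
                            hazard = hazard_config(),
                            stratify_by_study = TRUE, output_dir = NULL) {
  if (!is.null(csv) && !is.null(preset)) {
    abort("give exactly one input source: csv or preset")
  }
  if (is.null(csv)) {
    if (is.null(preset)) preset <- "overall"
    preset_margins(preset)  # validates the preset name
  }
  structure(list(csv = csv, preset = preset, n_patients = n_patients,
                 seed = as.integer(seed), score_opts = score_opts,
                 hazard = hazard, stratify_by_study = stratify_by_study,
                 output_dir = output_dir),
            class = "analysis_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort("[stage: ", stage, "] ", conditionMessage(e))
  })
}

# Fit wrapper: inestimable models (empty stratum, no events, collinearity)
# become flagged blank rows instead of aborting the whole run.
safe_fit <- function(...) {
  tryCatch(fit_cox(...), error = function(e) {
    structure(list(error = conditionMessage(e)), class = "cox_fit_failed")
  })
}

fit_row <- function(fit, scope, model, term_label, term_match = NULL) {
  blank <- data.frame(scope = scope, model = model, term = term_label,
                      hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, lr_chisq = NA_real_,
                      n = NA_integer_, n_events = NA_integer_,
                      note = NA_character_)
  if (inherits(fit, "cox_fit_failed")) {
    blank$note <- fit$error
    return(blank)
  }
  tt <- fit$terms
  row <- if (is.null(term_match)) tt[1L, ] else tt[grepl(term_match, tt$term), ][1L, ]
  blank$hr <- row$hr; blank$ci_low <- row$ci_low; blank$ci_high <- row$ci_high
  blank$p <- row$p; blank$lr_chisq <- fit$lr_chisq
  blank$n <- fit$n; blank$n_events <- fit$n_events
  blank
}

prepare_cohort <- function(cfg) {
  cohort <- with_stage("load", {
    if (!is.null(cfg$csv)) {
      coh <- read_cohort(cfg$csv)
      if ("core_id" %in% names(coh)) {
        agg <- aggregate_cores(coh)
        clin_cols <- setdiff(names(coh), c(names(agg), "core_id"))
        first <- coh[!duplicated(coh$patient_id),
                     c("patient_id", clin_cols), drop = FALSE]
        coh <- merge(agg, first, by = "patient_id", sort = TRUE)
      }
      coh
    } else {
      generate_cohort(cohort_config(n_patients = cfg$n_patients,
                                    preset = cfg$preset, seed = cfg$seed),
                      hz = cfg$hazard, opts = cfg$score_opts)
    }
  })
  cohort <- with_stage("score", {
    opts <- cfg$score_opts
    her2_in <- if (opts$her2_coding == "clinical_binary") {
      cohort$her2_clinical_pos
    } else {
      cohort$her2_herceptest
    }
    cohort$ihc4 <- compute_ihc4(cohort$er_pct, cohort$pr_pct,
                                cohort$ki67_pct, her2_in, opts)
    cohort$c_score <- compute_c_score(cohort$age_years, cohort$tumor_size_mm,
                                      cohort$grade, cohort$positive_nodes, opts)
    cohort$predict_score <- compute_predict_score(cohort$age_years,
                                                  cohort$tumor_size_mm,
                                                  cohort$grade,
                                                  cohort$positive_nodes)
    cohort
  })
  cohort$subtype <- with_stage("subtype",
    as.character(classify_cohort(cohort, cfg$score_opts)))
  cohort
}

#' Run the full prognostic-score comparison analysis
#'
#' Executes, in order: load or generate the cohort (aggregating core-level
#' input to patient level), score computation, subtype classification,
#' chemotherapy/complete-case exclusions, 10-year administrative truncation,
#' per-SD standardisation and IHC4 categorisation on the pooled analysis
#' cohort, the univariable and multivariable Cox model suite with
#' LR-chi-square bookkeeping, the nested Delta-LR comparison of the C-score
#' vs the PREDICT-score, the subtype-heterogeneity test, the high/low IHC4
#' comparisons within subtype, and the Kaplan-Meier suites (subtype,
#' quartiles, quartiles by nodal status, high/low).  All randomness lives in
#' cohort generation, so the report is a deterministic function of
#' (config, seed).
#'
#' @param cfg An [analysis_config()].
#' @return An object of class `analysis_report` (also written to
#'   `cfg$output_dir` when set; see [write_report()]).
#' @export
#' @examples
#' rep <- run_full_analysis(analysis_config(n_patients = 400, seed = 2,
#'                                          stratify_by_study = FALSE))
#' rep$table2[1:4, ]
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  cohort <- prepare_cohort(cfg)

  required <- c("time_years", "event", "ihc4", "c_score", "predict_score",
                "age_years", "endocrine_therapy")
  analysis <- with_stage("exclusions", apply_exclusions(cohort, required))
  exclusions <- attr(analysis, "exclusions")
  analysis <- with_stage("truncate", truncate_at_10y(analysis))

  analysis <- with_stage("derive", {
    # pooled-cohort standardisation, quartiles and the mean + 1 SD cut
    analysis$ihc4_z <- as.numeric(standardize_per_sd(analysis$ihc4))
    analysis$c_score_z <- as.numeric(standardize_per_sd(analysis$c_score))
    analysis$predict_score_z <- as.numeric(standardize_per_sd(analysis$predict_score))
    analysis$ihc4_quartile <- as.character(assign_quartiles(analysis$ihc4))
    dich <- dichotomize_mean_plus_sd(analysis$ihc4)
    analysis$ihc4_high <- as.integer(dich$high)
    attr(analysis, "ihc4_high_threshold") <- dich$threshold
    analysis$node_status <- ifelse(analysis$positive_nodes > 0,
                                   "node_positive", "node_negative")
    analysis
  })

  scopes <- list(combined = analysis)
  multi_study <- length(unique(analysis$study)) > 1L
  if (cfg$stratify_by_study && multi_study) {
    scopes <- c(scopes, split(analysis, analysis$study))
  }

  table2 <- with_stage("models", {
    rows <- list()
    for (sc in names(scopes)) {
      dat <- scopes[[sc]]
      adj <- c("age_years", "endocrine_therapy",
               if (sc == "combined" && multi_study) "study")
      sub_dat <- dat[dat$subtype %in% c("A_LIKE", "B_LIKE"), , drop = FALSE]
      sub_dat$subtype <- factor(sub_dat$subtype, levels = c("A_LIKE", "B_LIKE"))
      rows <- c(rows, list(
        fit_row(safe_fit(sub_dat, "subtype"), sc,
                "univariable", "subtype B-like vs A-like", "B_LIKE"),
        fit_row(safe_fit(dat, "ihc4_z"), sc, "univariable", "IHC4-score / 1 SD"),
        fit_row(safe_fit(dat, "c_score_z"), sc, "univariable", "C-score / 1 SD"),
        fit_row(safe_fit(dat, "predict_score_z"), sc, "univariable",
                "PREDICT-score / 1 SD"),
        fit_row(safe_fit(dat, c("ihc4_z", "c_score_z", adj)), sc,
                "multivariable_ihc4_c", "IHC4-score / 1 SD", "ihc4_z"),
        fit_row(safe_fit(dat, c("ihc4_z", "c_score_z", adj)), sc,
                "multivariable_ihc4_c", "C-score / 1 SD", "c_score_z"),
        fit_row(safe_fit(dat, c("ihc4_z", "predict_score_z", adj)), sc,
                "multivariable_ihc4_predict", "IHC4-score / 1 SD", "ihc4_z"),
        fit_row(safe_fit(dat, c("ihc4_z", "predict_score_z", adj)), sc,
                "multivariable_ihc4_predict", "PREDICT-score / 1 SD",
                "predict_score_z"),
        fit_row(safe_fit(sub_dat, c("subtype", "predict_score_z", adj)), sc,
                "multivariable_subtype_predict", "subtype B-like vs A-like",
                "B_LIKE"),
        fit_row(safe_fit(sub_dat, c("subtype", "predict_score_z", adj)), sc,
                "multivariable_subtype_predict", "PREDICT-score / 1 SD",
                "predict_score_z")
      ))
      for (st in c("A_LIKE", "B_LIKE")) {
        dst <- dat[dat$subtype == st, , drop = FALSE]
        model <- paste0("multivariable_", tolower(st), "_only")
        rows <- c(rows, list(
          fit_row(safe_fit(dst, c("ihc4_z", "predict_score_z", adj)), sc,
                  model, "IHC4-score / 1 SD", "ihc4_z"),
          fit_row(safe_fit(dst, c("ihc4_z", "predict_score_z", adj)), sc,
                  model, "PREDICT-score / 1 SD", "predict_score_z")))
      }
    }
    do.call(rbind, rows)
  })

  delta_lr <- with_stage("delta_lr", {
    adj <- c("age_years", "endocrine_therapy", if (multi_study) "study")
    full <- fit_cox(analysis, c("ihc4_z", "c_score_z", "predict_score_z", adj))
    no_c <- fit_cox(analysis, c("ihc4_z", "predict_score_z", adj))
    no_p <- fit_cox(analysis, c("ihc4_z", "c_score_z", adj))
    list(c_score = compare_nested(full, no_c),
         predict_score = compare_nested(full, no_p))
  })

  heterogeneity <- with_stage("heterogeneity", {
    adj <- c("predict_score_z", "age_years", "endocrine_therapy",
             if (multi_study) "study")
    tryCatch(heterogeneity_test(analysis, "ihc4_z", "subtype", adj)[
               c("p_value", "delta_lr_chisq", "df")],
             error = function(e) list(error = conditionMessage(e)))
  })

  table3 <- with_stage("table3", {
    rows <- list()
    for (sc in names(scopes)) {
      dat <- scopes[[sc]]
      adj <- c("predict_score_z", "age_years", "endocrine_therapy",
               if (sc == "combined" && multi_study) "study")
      for (st in c("A_LIKE", "B_LIKE")) {
        dst <- dat[dat$subtype == st, , drop = FALSE]
        counts <- table(factor(dst$ihc4_high, levels = 0:1))
        evs <- tapply(dst$event, factor(dst$ihc4_high, levels = 0:1), sum)
        row <- fit_row(safe_fit(dst, c("ihc4_high", adj)), sc,
                       paste0(tolower(st)), "high vs low IHC4-score",
                       "ihc4_high")
        row$cases_low <- as.integer(counts["0"])
        row$events_low <- as.integer(evs["0"])
        row$cases_high <- as.integer(counts["1"])
        row$events_high <- as.integer(evs["1"])
        rows <- c(rows, list(row))
      }
      # cross-subtype contrast: A-like/high IHC4 vs B-like/low IHC4 reference
      dx <- dat[(dat$subtype == "B_LIKE" & dat$ihc4_high == 0) |
                  (dat$subtype == "A_LIKE" & dat$ihc4_high == 1), , drop = FALSE]
      dx$a_high <- as.integer(dx$subtype == "A_LIKE")
      row <- fit_row(safe_fit(dx, c("a_high", adj)), sc, "cross_subtype",
                     "A-like/high vs B-like/low IHC4", "a_high")
      row$cases_low <- sum(dx$a_high == 0); row$events_low <- sum(dx$event[dx$a_high == 0])
      row$cases_high <- sum(dx$a_high == 1); row$events_high <- sum(dx$event[dx$a_high == 1])
      rows <- c(rows, list(row))
    }
    do.call(rbind, rows)
  })

  km <- with_stage("km", {
    sub_dat <- analysis[analysis$subtype %in% c("A_LIKE", "B_LIKE"), , drop = FALSE]
    list(subtype = km_logrank(sub_dat, "subtype"),
         quartiles = km_logrank(analysis, "ihc4_quartile"),
         quartiles_by_node = km_logrank(analysis, "ihc4_quartile",
                                        strata = "node_status"),
         high_low = km_logrank(analysis, "ihc4_high"))
  })

  report <- structure(
    list(config = cfg,
         counts = c(exclusions,
                    unclassified = sum(analysis$subtype == "UNCLASSIFIED"),
                    events = sum(analysis$event)),
         ihc4_high_threshold = attr(analysis, "ihc4_high_threshold"),
         table2 = table2, table3 = table3, delta_lr = delta_lr,
         heterogeneity = heterogeneity, km = km, analysis_cohort = analysis),
    class = "analysis_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Prognostic-score analysis report\n")
  cat(sprintf("  patients in: %d | chemo excluded: %d | incomplete: %d | analyzed: %d\n",
              x$counts["input"], x$counts["chemotherapy"],
              x$counts["incomplete"], x$counts["analyzed"]))
  cat(sprintf("  events (10y): %d | unclassified luminal: %d\n",
              x$counts["events"], x$counts["unclassified"]))
  uni <- x$table2[x$table2$scope == "combined" & x$table2$model == "univariable", ]
  cat("  Univariable (combined):\n")
  for (i in seq_len(nrow(uni))) {
    cat(sprintf("    %-28s HR %.2f (%.2f-%.2f)  LRchi2 %.1f\n",
                uni$term[i], uni$hr[i], uni$ci_low[i], uni$ci_high[i],
                uni$lr_chisq[i]))
  }
  if (!is.null(x$heterogeneity$p_value)) {
    cat(sprintf("  P-heterogeneity (IHC4 x subtype): %.2f\n",
                x$heterogeneity$p_value))
  }
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Emits `table2.csv` (score/subtype model matrix), `table3.csv` (high/low
#' IHC4 within subtype), per-suite KM step-function tables, `exclusions.csv`,
#' and a `manifest.json` echoing the configuration, resolved seeds, model
#' comparison statistics and conservation counts.  Output is a pure function
#' of the report object, so reruns are byte-identical.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- options(scipen = 0, digits = 15)
  on.exit(options(old))
  utils::write.csv(report$table2, file.path(dir, "table2.csv"), row.names = FALSE)
  utils::write.csv(report$table3, file.path(dir, "table3.csv"), row.names = FALSE)
  utils::write.csv(data.frame(stage = names(report$counts),
                              n = as.integer(report$counts)),
                   file.path(dir, "exclusions.csv"), row.names = FALSE)
  km_tables <- list(subtype = report$km$subtype, quartiles = report$km$quartiles,
                    high_low = report$km$high_low)
  for (nm in names(km_tables)) {
    utils::write.csv(km_tables[[nm]]$curves,
                     file.path(dir, paste0("km_", nm, ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(report$km$quartiles_by_node)) {
    utils::write.csv(report$km$quartiles_by_node[[nm]]$curves,
                     file.path(dir, paste0("km_quartiles_", nm, ".csv")),
                     row.names = FALSE)
  }
  cfg <- report$config
  manifest <- list(
    input = if (is.null(cfg$csv)) list(preset = cfg$preset,
                                       n_patients = cfg$n_patients)
            else list(csv = cfg$csv),
    seed = cfg$seed,
    stage_seeds = list(markers = child_seed(cfg$seed, 1L),
                       clinical = child_seed(cfg$seed, 2L),
                       survival = child_seed(cfg$seed, 3L)),
    score_options = unclass(cfg$score_opts),
    counts = as.list(report$counts),
    ihc4_high_threshold = report$ihc4_high_threshold,
    delta_lr_chisq = report$delta_lr,
    heterogeneity = report$heterogeneity,
    logrank = lapply(km_tables, function(k) list(chisq = k$logrank_chisq,
                                                 df = k$df, p = k$p)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Sensitivity analysis: reclassify subtype at the 1% ER/PR threshold
#'
#' Reruns the subtype-dependent analyses with hormone-receptor positivity
#' redefined as >= 1% positive cells (instead of > 10%), and returns a
#' cross-tabulation of subtype labels under the two conventions.  Because
#' relaxing the threshold can only add receptor-positive calls, no patient
#' moves from B-like to A-like.
#'
#' @param cfg An [analysis_config()] (its `score_opts` threshold is taken as
#'   the primary convention, normally 10).
#' @return A list with `crosstab` (primary threshold rows x sensitivity
#'   columns), `report` (the reanalysis under the 1% rule), and the two
#'   label vectors.
#' @export
sensitivity_reclassification <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  cohort <- prepare_cohort(cfg)
  opts1 <- cfg$score_opts
  opts1$er_pr_positivity_threshold <- 1
  lab10 <- classify_cohort(cohort, cfg$score_opts, on_nonluminal = "label")
  lab1 <- classify_cohort(cohort, opts1, on_nonluminal = "label")
  crosstab <- table(primary = lab10, sensitivity = lab1)
  cfg1 <- cfg
  cfg1$score_opts <- opts1
  cfg1$output_dir <- NULL
  list(crosstab = crosstab, report = run_full_analysis(cfg1),
       labels_primary = lab10, labels_sensitivity = lab1)
}
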