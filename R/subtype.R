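#' Marker positivity from clinical record or image-analysis percentage
#'
#' ER/PR status is taken from the binary clinical-record status when present;
#' otherwise the image-analysis percentage is compared against the configured
#' cut-off.  Under the historical 10% convention (Allred score > 2) positivity
#' means *strictly more than* 10% positive cells; under the modern 1%
#' convention it means *at least* 1%.
#'
#' @param pct Percent positive nuclei, 0-100 (may contain `NA` when a
#'   clinical status is supplied for that patient).
#' @param clinical Optional binary clinical-record status (0/1/`NA`).
#' @param threshold Positivity cut-off in percent: 10 (exclusive) or 1
#'   (inclusive).
#' @return Logical vector of positivity calls.
#' @export
marker_positive <- function(pct, clinical = NULL, threshold = 10) {
  if (!threshold %in% c(10, 1)) abort("threshold must be 10 or 1")
  pos <- if (threshold == 10) pct > threshold else pct >= threshold
  if (!is.null(clinical)) {
    assert_flag(clinical, "clinical status")
    use_clin <- !is.na(clinical)
    pos[use_clin] <- clinical[use_clin] == 1
  }
  if (anyNA(pos)) abort("marker status undeterminable: no percentage or clinical status")
  pos
}

#' Classify luminal A-like / B-like surrogate subtype
#'
#' Implements the St Gallen surrogate definition on binary marker categories:
#'
#' * **A-like**: ER+ *and* PR+ (homogeneous hormone-receptor expression),
#'   HER2-negative, and low proliferating (image-analysis KI67 <= 12%).
#' * **B-like**: ER+ and/or PR+, and either high proliferating
#'   (KI67 > 12%) or HER2-positive.
#'
#' The 12% KI67 cut-off is the image-analysis threshold (equivalent to a
#' visual score of roughly 25%) that best discriminates survival in this
#' setting.  Luminal tumours matching neither rule — HER2-negative, low
#' proliferating, but with only one hormone receptor positive — are returned
#' as `UNCLASSIFIED` and excluded from subtype-specific analyses.  The two
#' named rules are disjoint by construction.  Tumours with both receptors
#' negative are not luminal; by default this is an error.
#'
#' @param er_pos,pr_pos,her2_pos Logical (or 0/1) marker statuses.
#' @param ki67_pct Image-analysis KI67 percentage, 0-100.
#' @param ki67_cutoff Proliferation cut-off in percent (default 12).
#' @param on_nonluminal What to do with ER-/PR- tumours: `"error"` (default),
#'   `"na"`, or `"label"` (returns level `NON_LUMINAL`, used by the
#'   sensitivity cross-tabulation where a patient can be luminal under one
#'   positivity threshold but not the other).
#' @return Factor with levels `A_LIKE`, `B_LIKE`, `UNCLASSIFIED` (plus
#'   `NON_LUMINAL` when `on_nonluminal = "label"`).
#' @export
#' @examples
#' classify_subtype(TRUE, TRUE, FALSE, 10)   # A_LIKE
#' classify_subtype(TRUE, FALSE, TRUE, 5)    # B_LIKE
classify_subtype <- function(er_pos, pr_pos, her2_pos, ki67_pct,
                             ki67_cutoff = 12,
                             on_nonluminal = c("error", "na", "label")) {
  on_nonluminal <- match.arg(on_nonluminal)
  a <- recycle_args(er_pos = as.logical(er_pos), pr_pos = as.logical(pr_pos),
                    her2_pos = as.logical(her2_pos), ki67_pct = ki67_pct)
  assert_numeric_in(a$ki67_pct, 0, 100, "ki67_pct")
  nonlum <- !a$er_pos & !a$pr_pos
  if (any(nonlum) && on_nonluminal == "error") {
    abort("ER- and PR- tumours are not luminal (", sum(nonlum), " row(s)); ",
          "use on_nonluminal = 'na' or 'label' to keep them")
  }
  high_prolif <- a$ki67_pct > ki67_cutoff
  lab <- rep(NA_character_, length(a$er_pos))
  lab[(a$er_pos | a$pr_pos) & (high_prolif | a$her2_pos)] <- "B_LIKE"
  lab[a$er_pos & a$pr_pos & !a$her2_pos & !high_prolif] <- "A_LIKE"
  lab[(a$er_pos | a$pr_pos) & is.na(lab)] <- "UNCLASSIFIED"
  if (on_nonluminal == "label") lab[nonlum] <- "NON_LUMINAL"
  levels <- c("A_LIKE", "B_LIKE", "UNCLASSIFIED",
              if (on_nonluminal == "label") "NON_LUMINAL")
  factor(lab, levels = levels)
}

#' Classify subtype for a patient-level cohort table
#'
#' Convenience wrapper resolving ER/PR positivity (under the 10% convention:
#' clinical-record status when present, else image percentage > 10; under the
#' 1% sensitivity convention: image percentage >= 1, ignoring the
#' Allred-derived record statuses) and HER2 positivity (clinical status when
#' present, else averaged Herceptest >= 3) before calling
#' [classify_subtype()].
#'
#' @param cohort Patient-level data frame (see [read_cohort()] for columns).
#' @param opts A [score_options()] object.
#' @param on_nonluminal Passed to [classify_subtype()].
#' @return Factor of subtype labels, one per row of `cohort`.
#' @export
classify_cohort <- function(cohort, opts = score_options(),
                            on_nonluminal = "error") {
  thr <- opts$er_pr_positivity_threshold
  # Clinical-record ER/PR statuses encode the historical Allred-based 10%
  # rule, so they only stand in under the 10% convention; the 1% sensitivity
  # convention re-derives positivity from the image percentages directly.
  er_clin <- if (thr == 10) cohort$er_clinical_pos
  pr_clin <- if (thr == 10) cohort$pr_clinical_pos
  er <- marker_positive(cohort$er_pct, er_clin, thr)
  pr <- marker_positive(cohort$pr_pct, pr_clin, thr)
  her2 <- if (!is.null(cohort$her2_clinical_pos) && !anyNA(cohort$her2_clinical_pos)) {
    cohort$her2_clinical_pos == 1
  } else {
    h <- cohort$her2_herceptest >= 3
    if (!is.null(cohort$her2_clinical_pos)) {
      k <- !is.na(cohort$her2_clinical_pos)
      h[k] <- cohort$her2_clinical_pos[k] == 1
    }
    h
  }
  classify_subtype(er, pr, her2, cohort$ki67_pct, on_nonluminal = on_nonluminal)
}
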