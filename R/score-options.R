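#' Scoring conventions for the IHC4 and clinical scores
#'
#' Bundles the conventions that are not fully pinned down by the published
#' score definitions and that a user may legitimately want to vary:
#'
#' * `ki67_unit`: unit of the KI67 value entering the `ln(1 + 10 * KI67)`
#'   term of the IHC4 score.  `"percent"` (default) uses the 0-100 image
#'   analysis percentage directly; `"fraction"` divides by 100 first, matching
#'   the original visual-score convention.  The percent default is supported
#'   by back-calculation against the published cohort summary statistics of
#'   the image-analysis score (mean 33, SD 65, maximum 289), which are
#'   inconsistent with a fraction-scaled KI67 term.
#' * `her2_coding`: `"herceptest_ordinal"` (default) feeds the patient-level
#'   average of the ordinal 0/1+/2+/3+ Herceptest score (a real in \[0, 3\])
#'   into the 0.586 HER2 term; `"clinical_binary"` feeds the 0/1
#'   clinical-record HER2 status instead.
#' * `er_pr_positivity_threshold`: ER/PR positivity cut-off in percent for
#'   subtype classification when no clinical-record status is available.
#'   The two published conventions are supported: 10 (Allred > 2, i.e.
#'   strictly more than 10% positive cells; default) and 1 (at least 1%
#'   positive cells, the modern guideline used as sensitivity analysis).
#' * `c_score_bracket_convention`: whether the 0.930 multiplier of the
#'   C-score applies only to the `0.497 * T(1-2cm)` size term exactly as the
#'   equation is printed (`"as_printed"`, default) or to the whole bracketed
#'   group of size/grade/age/treatment terms (`"whole_bracket"`).
#'
#' @param ki67_unit `"percent"` or `"fraction"`.
#' @param her2_coding `"herceptest_ordinal"` or `"clinical_binary"`.
#' @param er_pr_positivity_threshold 10 or 1 (percent).
#' @param c_score_bracket_convention `"as_printed"` or `"whole_bracket"`.
#' @return An object of class `score_options`.
#' @export
#' @examples
#' score_options()
#' score_options(er_pr_positivity_threshold = 1)
score_options <- function(ki67_unit = c("percent", "fraction"),
                          her2_coding = c("herceptest_ordinal", "clinical_binary"),
                          er_pr_positivity_threshold = 10,
                          c_score_bracket_convention = c("as_printed", "whole_bracket")) {
  ki67_unit <- match.arg(ki67_unit)
  her2_coding <- match.arg(her2_coding)
  c_score_bracket_convention <- match.arg(c_score_bracket_convention)
  if (!er_pr_positivity_threshold %in% c(10, 1)) {
    abort("er_pr_positivity_threshold must be 10 or 1 (the two published conventions)")
  }
  structure(
    list(ki67_unit = ki67_unit,
         her2_coding = her2_coding,
         er_pr_positivity_threshold = er_pr_positivity_threshold,
         c_score_bracket_convention = c_score_bracket_convention),
    class = "score_options"
  )
}

#' @export
print.score_options <- function(x, ...) {
  cat("Score options:\n")
  cat("  KI67 unit in IHC4 ln-term :", x$ki67_unit, "\n")
  cat("  HER2 coding in IHC4       :", x$her2_coding, "\n")
  cat("  ER/PR positivity cut-off  :", x$er_pr_positivity_threshold, "%",
      if (x$er_pr_positivity_threshold == 10) "(exclusive, Allred > 2)" else "(inclusive)", "\n")
  cat("  C-score bracket convention:", x$c_score_bracket_convention, "\n")
  invisible(x)
}
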