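# CSV cohort dialect.  One row per patient (or per core, when a `core_id`
# column is present), comma-separated, header row, empty field = missing.
# Column dictionary:
#   patient_id        identifier, unique at patient level
#   core_id           core identifier (core-level files only)
#   er_pct, pr_pct, ki67_pct   percent positive nuclei, 0-100
#   her2_herceptest   Herceptest ordinal; 0-3 (patient-level averages are real)
#   er_clinical_pos, pr_clinical_pos, her2_clinical_pos   0/1 record status
#   age_years         years, > 0
#   tumor_size_mm     millimetres, > 0
#   grade             1, 2 or 3
#   positive_nodes    integer >= 0
#   endocrine_therapy, chemotherapy   0/1
#   study             PBCS or SEARCH
#   time_years        follow-up, > 0
#   event             0/1 breast-cancer death

cohort_numeric_ranges <- list(
  er_pct = c(0, 100), pr_pct = c(0, 100), ki67_pct = c(0, 100),
  her2_herceptest = c(0, 3), age_years = c(1e-9, 120),
  tumor_size_mm = c(1e-9, 500), grade = c(1, 3), positive_nodes = c(0, Inf),
  er_clinical_pos = c(0, 1), pr_clinical_pos = c(0, 1),
  her2_clinical_pos = c(0, 1), endocrine_therapy = c(0, 1),
  chemotherapy = c(0, 1), time_years = c(1e-9, Inf), event = c(0, 1)
)

#' Validate a cohort table against the CSV schema
#'
#' @param cohort Data frame as returned by [read_cohort()].
#' @param what Label used in error messages (e.g. the file path).
#' @return The validated cohort, invisibly.  Errors carry 1-based data row
#'   numbers (header excluded).
#' @export
validate_cohort <- function(cohort, what = "cohort") {
  known <- c("patient_id", "core_id", "study", "lp_true",
             names(cohort_numeric_ranges), "ihc4", "c_score", "predict_score",
             "ihc4_z", "subtype", "ihc4_quartile", "ihc4_high")
  unknown <- setdiff(names(cohort), known)
  if (length(unknown)) {
    abort(what, ": unknown column(s): ", paste(unknown, collapse = ", "))
  }
  if (!"patient_id" %in% names(cohort)) abort(what, ": missing patient_id column")
  core_level <- "core_id" %in% names(cohort)
  if (!core_level && anyDuplicated(cohort$patient_id)) {
    dup <- which(duplicated(cohort$patient_id))[1L]
    abort(what, ": duplicate patient_id '", cohort$patient_id[dup],
          "' at row ", dup)
  }
  for (col in intersect(names(cohort_numeric_ranges), names(cohort))) {
    x <- cohort[[col]]
    if (!is.numeric(x)) abort(what, ": column ", col, " must be numeric")
    rng <- cohort_numeric_ranges[[col]]
    bad <- which(!is.na(x) & (x < rng[1] | x > rng[2]))
    if (length(bad)) {
      abort(what, ": ", col, " = ", x[bad[1L]], " out of range [",
            rng[1], ", ", rng[2], "] at row ", bad[1L])
    }
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads and validates a patient-level or core-level cohort table in the
#' package's CSV dialect (empty fields are missing values).
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort("cohort file not found: ", path)
  cohort <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  validate_cohort(cohort, what = path)
  cohort
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]; the round trip is lossless for the documented
#' columns (numbers are written at full precision, missing values as empty
#' fields).
#'
#' @param cohort Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  old <- options(scipen = 0, digits = 15)
  on.exit(options(old))
  utils::write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
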