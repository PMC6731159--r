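#' Aggregate per-core marker measurements to patient level
#'
#' Tissue-microarray cores are scored individually; the patient-level value of
#' each marker is the arithmetic mean of that marker over the cores on which
#' it was measured.  Ordinal Herceptest scores (0/1+/2+/3+) are averaged as
#' real numbers, so the patient-level HER2 value lies in \[0, 3\].
#'
#' @param cores A data frame with one row per core.  Required columns:
#'   `er_pct`, `pr_pct`, `ki67_pct` (percent positive nuclei, 0-100) and
#'   `her2_herceptest` (0, 1, 2 or 3).  `NA` marks a marker not measured on a
#'   core.  An optional `patient_id` column groups cores by patient; without
#'   it all rows are treated as one patient.
#' @return A data frame with one row per patient carrying the averaged marker
#'   columns (and `patient_id` when supplied).  A marker missing on every
#'   core of a patient is returned as `NA`.
#' @export
#' @examples
#' aggregate_cores(data.frame(er_pct = c(60, 80), pr_pct = c(50, 50),
#'                            ki67_pct = c(5, 15), her2_herceptest = c(0, 1)))
aggregate_cores <- function(cores) {
  if (!is.data.frame(cores) || nrow(cores) == 0L) {
    abort("aggregate_cores() needs a non-empty data frame of core measurements")
  }
  markers <- c("er_pct", "pr_pct", "ki67_pct", "her2_herceptest")
  missing_cols <- setdiff(markers, names(cores))
  if (length(missing_cols)) {
    abort("missing core columns: ", paste(missing_cols, collapse = ", "))
  }
  for (m in markers) {
    # an all-NA marker column reads back as logical; keep it numeric
    if (is.logical(cores[[m]]) && all(is.na(cores[[m]]))) {
      cores[[m]] <- as.numeric(cores[[m]])
    }
  }
  assert_numeric_in(cores$er_pct, 0, 100, "er_pct", allow_na = TRUE)
  assert_numeric_in(cores$pr_pct, 0, 100, "pr_pct", allow_na = TRUE)
  assert_numeric_in(cores$ki67_pct, 0, 100, "ki67_pct", allow_na = TRUE)
  if (!all(cores$her2_herceptest %in% c(0, 1, 2, 3, NA))) {
    abort("her2_herceptest core scores must be 0, 1, 2 or 3")
  }
  if (any(apply(is.na(cores[markers]), 1L, all))) {
    abort("every core must have at least one marker measured")
  }
  id <- if ("patient_id" %in% names(cores)) cores$patient_id else rep(1L, nrow(cores))
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(cores)), id), function(i) {
    data.frame(patient_id = id[i[1L]],
               as.list(vapply(cores[i, markers], mean_na, numeric(1))))
  }))
  rownames(out) <- NULL
  if (!"patient_id" %in% names(cores)) out$patient_id <- NULL
  out
}

#' Compute the IHC4 prognostic score
#'
#' The IHC4 score combines quantitative immunohistochemical measurements of
#' the four routine breast-cancer markers into a single continuous prognostic
#' index:
#'
#' \deqn{94.7 \times \{-0.100\,ER_{10} - 0.079\,PR_{10} + 0.586\,HER2
#'       + 0.240\,\ln(1 + 10 \times KI67)\}}
#'
#' where \eqn{ER_{10} = ER\%/10} and \eqn{PR_{10} = PR\%/10} (image-analysis
#' percentages divided by 10, giving 0-10), HER2 is coded per
#' `opts$her2_coding`, and KI67 enters the log term per `opts$ki67_unit`.
#' Higher scores indicate worse prognosis: the score decreases in ER and PR
#' expression and increases in HER2 and proliferation.
#'
#' @param er_pct,pr_pct Percent positive nuclei, 0-100.
#' @param ki67_pct Percent positive nuclei, 0-100 (always supplied in
#'   percent; `opts$ki67_unit` controls the unit inside the log term).
#' @param her2 HER2 input: averaged Herceptest ordinal in \[0, 3\] under
#'   `"herceptest_ordinal"` coding, or 0/1 clinical status under
#'   `"clinical_binary"`.
#' @param opts A [score_options()] object.
#' @return Numeric vector of IHC4 scores.
#' @export
#' @examples
#' compute_ihc4(62, 57, 9, 0)   # cohort medians, HER2 negative
compute_ihc4 <- function(er_pct, pr_pct, ki67_pct, her2, opts = score_options()) {
  stopifnot(inherits(opts, "score_options"))
  for (comp in c("er_pct", "pr_pct", "ki67_pct", "her2")) {
    v <- get(comp)
    if (is.null(v) || length(v) == 0L || anyNA(v)) {
      abort("IHC4 component '", comp, "' is missing")
    }
  }
  a <- recycle_args(er_pct = er_pct, pr_pct = pr_pct,
                    ki67_pct = ki67_pct, her2 = her2)
  if (any(a$ki67_pct < 0)) abort("ki67_pct must be non-negative")
  assert_numeric_in(a$er_pct, 0, 100, "er_pct")
  assert_numeric_in(a$pr_pct, 0, 100, "pr_pct")
  assert_numeric_in(a$ki67_pct, 0, 100, "ki67_pct")
  hi <- if (opts$her2_coding == "clinical_binary") 1 else 3
  assert_numeric_in(a$her2, 0, hi, "her2")
  ki67 <- if (opts$ki67_unit == "percent") a$ki67_pct else a$ki67_pct / 100
  94.7 * (-0.100 * (a$er_pct / 10) +
          -0.079 * (a$pr_pct / 10) +
           0.586 * a$her2 +
           0.240 * log(1 + 10 * ki67))
}

#' Compute the clinical treatment score (C-score)
#'
#' Linear score over the classical clinical prognostic factors:
#'
#' \deqn{100 \times \{0.417\,N_{1-3} + 1.566\,N_{4+} +
#'   [0.930 \times (0.497\,T_{1-2}) + 0.882\,T_{2-3} + 1.838\,T_{>3} +
#'    0.559\,Gr_2 + 0.970\,Gr_3 + 0.130\,Age_{\ge 65} + 0.149\,AI]\}}
#'
#' with indicator categories: positive nodes 0 (reference) / 1-3 / 4+;
#' tumour size \eqn{\le}1 cm (reference) / >1-2 cm / >2-3 cm / >3 cm;
#' grade 1 reference; age dichotomised at 65 years (closed lower bound,
#' i.e. exactly 65 counts as \eqn{\ge 65}).  The aromatase-inhibitor vs.
#' tamoxifen term (AI) is fixed at 0 because per-patient endocrine regimen
#' is not modelled.  The score is non-negative and equals 0 exactly at the
#' full reference category.
#'
#' @param age_years Age at diagnosis in years (> 0).
#' @param tumor_size_mm Invasive tumour size in millimetres (> 0).
#' @param grade Histologic grade, 1, 2 or 3.
#' @param positive_nodes Number of involved lymph nodes (integer >= 0).
#' @param opts A [score_options()] object; `c_score_bracket_convention`
#'   selects how the 0.930 multiplier is grouped.
#' @return Numeric vector of C-scores.
#' @export
#' @examples
#' compute_c_score(70, 15, 2, 2)   # 156.821
compute_c_score <- function(age_years, tumor_size_mm, grade, positive_nodes,
                            opts = score_options()) {
  stopifnot(inherits(opts, "score_options"))
  for (comp in c("age_years", "tumor_size_mm", "grade", "positive_nodes")) {
    if (anyNA(get(comp))) abort("C-score component '", comp, "' is missing")
  }
  a <- recycle_args(age_years = age_years, tumor_size_mm = tumor_size_mm,
                    grade = grade, positive_nodes = positive_nodes)
  if (any(a$tumor_size_mm <= 0)) abort("tumor_size_mm must be positive")
  if (any(a$positive_nodes < 0)) abort("positive_nodes must be non-negative")
  if (!all(a$grade %in% 1:3)) abort("grade must be 1, 2 or 3")

  n13 <- a$positive_nodes >= 1 & a$positive_nodes <= 3
  n4  <- a$positive_nodes >= 4
  cm  <- a$tumor_size_mm / 10
  t12 <- cm > 1 & cm <= 2
  t23 <- cm > 2 & cm <= 3
  t3  <- cm > 3
  inner <- 0.882 * t23 + 1.838 * t3 +
           0.559 * (a$grade == 2) + 0.970 * (a$grade == 3) +
           0.130 * (a$age_years >= 65) +
           0.149 * 0                      # AI term: regimen data not modelled
  size12 <- 0.497 * t12
  inner <- switch(opts$c_score_bracket_convention,
                  as_printed   = 0.930 * size12 + inner,
                  whole_bracket = 0.930 * (size12 + inner))
  100 * (0.417 * n13 + 1.566 * n4 + inner)
}

#' Compute the PREDICT (ER+) prognostic index
#'
#' Linear predictor of the PREDICT v1 breast-cancer prognostication model for
#' ER-positive disease, built from age, tumour size, nodal count and grade
#' (natural logarithms throughout, size in millimetres so that `Size/100` is
#' in decimetres as in the original model):
#'
#' \deqn{(34.53 (Age/10)^{-2} - 0.0287) +
#'       (-34.20 (Age/10)^{-2} \ln(Age/10) - 0.0510) +
#'       (0.7531 \ln(Size/100) + 1.5452) +
#'       (0.7069 \ln((Nodes+1)/10) + 1.3876) + 0.7467\,Grade}
#'
#' The screen-detected vs. interval term (-0.2763) is omitted (set to 0)
#' because detection mode is not modelled.  Grade enters numerically (1-3),
#' so the grade-3 minus grade-2 difference is exactly 0.7467.
#'
#' @inheritParams compute_c_score
#' @return Numeric vector of PREDICT linear-predictor values.
#' @export
#' @examples
#' compute_predict_score(50, 20, 2, 0)   # about 0.686
compute_predict_score <- function(age_years, tumor_size_mm, grade, positive_nodes) {
  for (comp in c("age_years", "tumor_size_mm", "grade", "positive_nodes")) {
    if (anyNA(get(comp))) abort("PREDICT component '", comp, "' is missing")
  }
  a <- recycle_args(age_years = age_years, tumor_size_mm = tumor_size_mm,
                    grade = grade, positive_nodes = positive_nodes)
  if (any(a$age_years <= 0)) abort("age_years must be positive")
  if (any(a$tumor_size_mm <= 0)) abort("tumor_size_mm must be positive")
  if (any(a$positive_nodes < 0)) abort("positive_nodes must be non-negative")
  if (!all(a$grade %in% 1:3)) abort("grade must be 1, 2 or 3")
  dage <- a$age_years / 10
  (34.53 * dage^-2 - 0.0287) +
    (-34.20 * dage^-2 * log(dage) - 0.0510) +
    (0.7531 * log(a$tumor_size_mm / 100) + 1.5452) +
    (0.7069 * log((a$positive_nodes + 1) / 10) + 1.3876) +
    0.7467 * a$grade
}
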