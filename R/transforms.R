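#' Standardise a score to per-standard-deviation units
#'
#' Centres and scales by the sample standard deviation (n-1 denominator) of
#' the analysis cohort, so a Cox coefficient on the result is a log hazard
#' ratio per 1 SD of the score.
#'
#' @param values Numeric vector with at least two finite values and nonzero
#'   spread.
#' @return Numeric vector with mean 0 and sample SD 1; the cohort mean and SD
#'   are attached as attributes `center` and `scale`.
#' @export
standardize_per_sd <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) abort("need at least two finite values to standardize")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) abort("cannot standardize a zero-variance vector")
  out <- (values - mean(v)) / s
  attr(out, "center") <- mean(v)
  attr(out, "scale") <- s
  out
}

#' Dichotomise a score at the mean + 1 SD threshold
#'
#' The high-score group is everything strictly above mean + 1 sample SD; the
#' threshold itself is returned so the categorisation is reproducible on new
#' data.
#'
#' @inheritParams standardize_per_sd
#' @return A list with `high` (logical vector) and `threshold` (numeric).
#' @export
#' @examples
#' dichotomize_mean_plus_sd(c(0, 0, 0, 10))
dichotomize_mean_plus_sd <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) abort("need at least two finite values to dichotomize")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) abort("cannot dichotomize a zero-variance vector")
  thr <- mean(v) + s
  list(high = values > thr, threshold = thr)
}

#' Assign empirical quartile groups
#'
#' Bins values at the empirical 25th/50th/75th percentiles (type-7 quantiles).
#' Intervals are right-closed: a value exactly equal to a break is assigned to
#' the lower bin.  Quartile membership is invariant under strictly monotone
#' transformations of the input.
#'
#' @param values Numeric vector with at least four distinct finite values.
#' @return Ordered factor with levels `Q1` < `Q2` < `Q3` < `Q4`.
#' @export
#' @examples
#' assign_quartiles(1:8)
assign_quartiles <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 4L) abort("need at least four distinct values for quartiles")
  br <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  idx <- 1L + (values > br[1]) + (values > br[2]) + (values > br[3])
  factor(paste0("Q", idx), levels = paste0("Q", 1:4), ordered = TRUE)
}
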