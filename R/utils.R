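#' @keywords internal
"_PACKAGE"

# Internal assertion helpers.  All user-facing errors go through stop() with
# call. = FALSE so messages read as package diagnostics, not tracebacks.

abort <- function(...) stop(..., call. = FALSE)

assert_numeric_in <- function(x, lo, hi, what, allow_na = FALSE) {
  if (!is.numeric(x)) abort(what, " must be numeric")
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    abort(what, " out of range [", lo, ", ", hi, "]: ",
          paste(utils::head(x[bad], 3), collapse = ", "))
  }
  if (!allow_na && anyNA(x)) abort(what, " contains missing values")
  invisible(x)
}

assert_flag <- function(x, what) {
  if (!(is.logical(x) || all(x %in% c(0, 1, NA)))) {
    abort(what, " must be binary (0/1 or logical)")
  }
  invisible(x)
}

#' Derive a per-stage child seed from a global seed
#'
#' A single run-level seed is fanned out to independent stage seeds through a
#' fixed affine map modulo the Mersenne prime 2^31 - 1, so each pipeline stage
#' (markers, clinical factors, survival, ...) is individually reproducible and
#' stages do not share random streams.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (1, 2, 3, ...).
#' @return A positive integer seed strictly below 2^31.
#' @export
#' @examples
#' child_seed(1L, 1L)
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stage), length(stage) == 1L, stage >= 1)
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) * 48271 + 7919 * as.numeric(stage)
  as.integer(s %% m + 1)
}

# Recycle scalar arguments against a common length, erroring on mismatch.
recycle_args <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  for (nm in names(args)) {
    len <- length(args[[nm]])
    if (len == n) next
    if (len == 1L) args[[nm]] <- rep(args[[nm]], n)
    else abort("argument '", nm, "' has length ", len, ", expected 1 or ", n)
  }
  args
}
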