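# internal validation helpers -------------------------------------------------

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "ciliadyn_parameter_error")
  invisible(TRUE)
}

assert_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x <= max
  if (ok && integerish) ok <- abs(x - round(x)) < 1e-8
  assert_that(ok, sprintf(
    "`%s` must be a single finite %s in [%s, %s], got %s",
    name, if (integerish) "integer" else "number",
    format(min), format(max), paste(format(x), collapse = ", ")
  ))
  if (integerish) as.integer(round(x)) else x
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  assert_that(length(missing) == 0L, sprintf(
    "%s is missing required column(s): %s", what, paste(missing, collapse = ", ")
  ))
  invisible(df)
}

# run expr with a reproducible RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angles (degrees) into [0, 360)
wrap_deg <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

#' Standard error of the mean
#'
#' `sem()` is the sample standard deviation divided by the square root of the
#' number of observations, the error bar used throughout the package's
#' summaries. With fewer than two observations the s.e.m. is undefined and
#' `NA` is returned with a warning.
#'
#' @param x Numeric vector.
#' @return A single number, or `NA_real_` when `length(x) < 2`.
#' @examples
#' sem(c(10, 12, 11))
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) {
    warn("s.e.m. undefined for fewer than 2 observations; returning NA")
    return(NA_real_)
  }
  stats::sd(x) / sqrt(length(x))
}
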