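stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Geometric mean
#'
#' @param x Positive numeric vector.
#' @return The geometric mean `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("geometric mean requires finite positive values")
  exp(mean(log(x)))
}

#' Round half away from zero
#'
#' Display rounding used for report tables: exact halves round away from
#' zero (`37.75 -> 37.8`), unlike [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g", name, lower)
  if (x > upper)
    stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}
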