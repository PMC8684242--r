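#' Round half away from zero
#'
#' Fixed-precision rounding with halves rounded up (the convention used in
#' the design reports), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# percentage of a count over a denominator, rounded half-up to 2 decimals;
# NA (reported as em-dash downstream) when the denominator is zero
pct <- function(count, denom, digits = 2) {
  ifelse(denom > 0, round_half_up(100 * count / denom, digits), NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_field(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

check_positive <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && !anyNA(x) && all(if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop_field(field, if (strict) "must be strictly positive" else
      "must be non-negative")
  }
  invisible(x)
}
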