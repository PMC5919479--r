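#' Round half away from zero
#'
#' Deterministic half-up rounding used for every reported percentage in the
#' package. Base R's `round()` rounds half to even (IEC 60559), which cannot
#' reproduce clinically reported percentages such as 53/258 = 20.5426... ->
#' "20.5" together with 26/53 = 49.0566... -> "49.1" under a single rule;
#' published tables almost universally round half up. The 2x2 reconstruction
#' logic depends on this exact rule, so it lives in one place.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits (default 1, the precision of the
#'   published percentages).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(100 * 53 / 258) # 20.5
#' round_half_up(0.15, 1)        # 0.2 (base round() gives 0.1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Percentage of a count, rounded as reported
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimals (default 1).
#' @return half-up rounded percentage.
#' @export
pct <- function(k, n, digits = 1) round_half_up(100 * k / n, digits)

# internal input guards ------------------------------------------------------

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("rvload_invalid_input", "error")))
}

stop_missing_data <- function(msg, fields) {
  stop(errorCondition(msg,
    fields = fields,
    class = c("rvload_missing_data", "error")
  ))
}

check_positive <- function(x, name, strict = TRUE) {
  bad <- !is.na(x) & if (strict) x <= 0 else x < 0
  if (any(bad)) {
    stop_invalid(name, " must be strictly positive (got ", x[bad][1], ")")
  }
  invisible(x)
}
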