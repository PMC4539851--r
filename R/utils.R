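#' Round half away from zero
#'
#' Deterministic half-up rounding used for every printed percentage, in
#' contrast to [base::round()]'s round-half-to-even. A tiny epsilon absorbs
#' binary floating-point representation error so that values like
#' `83.005` round up as intended.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.005)   # 2.01
#' round(2.005, 2)        # 2 under banker's rounding
#' @export
round_half_up <- function(x, digits = 2) {
  z <- abs(x) * 10^digits
  z <- trunc(z + 0.5 + sqrt(.Machine$double.eps))
  sign(x) * z / 10^digits
}

#' Percentage of a total, half-up to two decimals
#'
#' @param count numerator count.
#' @param total denominator count; `NA` is returned when `total` is 0.
#' @return numeric percentage on the 0-100 scale, two decimals.
#' @examples
#' percent_of(2421, 3048) # 79.43
#' @export
percent_of <- function(count, total) {
  ifelse(total == 0, NA_real_, round_half_up(100 * count / total, 2))
}

# format a percentage for tab-delimited output ("-" when undefined)
fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.2f %%", x))

gene_length <- function(start, stop) stop - start + 1L

# shared bp between two closed intervals (<= 0 means disjoint)
shared_bp <- function(s1, e1, s2, e2) pmin(e1, e2) - pmax(s1, s2) + 1L

`%||%` <- function(a, b) if (is.null(a)) b else a
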