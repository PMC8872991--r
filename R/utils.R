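#' Percentage as reported in screening tables
#'
#' The single code path every summary table uses to turn a count and a total
#' into a percentage: 100 * count / total rounded to one decimal.
#'
#' @param count numerator count.
#' @param total denominator count.
#' @return numeric percentage, one decimal.
#' @export
pct <- function(count, total) round(100 * count / total, 1)

# "median (q25-q75)" string, fixed number of decimals
fmt_median_iqr <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  sprintf("%.*f (%.*f-%.*f)", digits, q[1], digits, q[2], digits, q[3])
}

# "count (pct)" string using the shared pct() path
fmt_count_pct <- function(count, total) {
  sprintf("%d (%.1f)", count, pct(count, total))
}
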