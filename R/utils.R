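#' Round half away from zero
#'
#' Presentation rounding for currency and percentages.  Base R's `round()`
#' rounds half to even; reimbursement tables and the reported cost figures
#' use commercial (half-up) rounding, so results are carried unrounded through
#' every computation and only rounded half-up when printed or compared to a
#' published figure.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, i.e. cents).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(2.675)   # 2.68, where round(2.675, 2) gives 2.67
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Format euro amounts for print methods.
format_eur <- function(x, digits = 2) {
  paste0("€", formatC(round_half_up(x, digits), format = "f", digits = digits))
}

# Named integer vector with one (possibly zero) entry per diagnostic state.
count_by_state <- function(x) {
  out <- table(factor(x, levels = dx_states()))
  stats::setNames(as.integer(out), dx_states())
}

stopifnot_cohort_nonempty <- function(cohort, what) {
  if (nrow(cohort) == 0) {
    rlang::abort(paste0(what, " requires a non-empty cohort"))
  }
}
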