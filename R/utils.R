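#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the reported percentage
#' cells: 0.125 rounds to 0.13 at two digits, unlike [base::round()], which
#' rounds half to even. A small epsilon absorbs binary representation error
#' of decimal fractions before the floor.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(2.675, 2) # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of posts mentioning an adverse event
#'
#' The table-cell formula: percentage = (number of posts mentioning the
#' adverse event for a medication / total posts about the medication) x 100,
#' rounded half-up.
#'
#' @param n posts mentioning the adverse event.
#' @param total total posts about the medication.
#' @param digits decimal places (2 for table cells, 1 for narrative shares).
#' @return numeric percentage; `NA` where `total` is zero (undefined).
#' @export
#' @examples
#' pct_cell(210, 4885) # 4.30
pct_cell <- function(n, total, digits = 2) {
  out <- round_half_up(100 * n / total, digits)
  out[total == 0] <- NA_real_
  out
}

# internal: stop with a classed error, keeping call sites terse
ae_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "aeminer_error"))
}
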