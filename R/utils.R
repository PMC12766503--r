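#' Round half away from zero
#'
#' Base R's `round()` rounds halves to even; survey-style reports
#' conventionally round halves away from zero (25.5 -> 26, not 25.17 -> 25.2
#' issues aside). All printed percentages in this package use this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(100 * 36 / 143)      # 25
#' round_half_up(100 * 1497 / 4844, 2) # 30.90
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(msg) stop(errorCondition(msg, class = c("screensift_config_error", "error")))

abort_input <- function(msg) stop(errorCondition(msg, class = c("screensift_input_error", "error")))
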