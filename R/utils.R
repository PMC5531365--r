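#' Round half away from zero
#'
#' Report-grade rounding: ties go away from zero (so 0.535 -> 0.54), matching
#' the convention of the clinical software whose tables the reports emulate,
#' rather than base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt2 <- function(x) formatC(round_half_away(x, 2), format = "f", digits = 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop_domain(msg)
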