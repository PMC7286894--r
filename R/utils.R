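`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(..., call. = FALSE)

#' Round half away from zero
#'
#' Fixed-precision rounding where ties go away from zero (so 0.005 -> 0.01),
#' matching how derived figures are conventionally printed in genomics
#' reports, rather than base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# run code under a temporary RNG seed without touching global RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a stream-specific 31-bit sub-seed from a master seed
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) %% 1009L
}
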