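# Internal numeric / formatting helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published tables in this field
#' are formatted with conventional half-up rounding, so reporting layers
#' use this helper instead.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pc_stop <- function(...) stop(..., call. = FALSE)

pc_warn <- function(...) warning(..., call. = FALSE)

# Deterministic seed derivation: keeps derived seeds inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647L)
}
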