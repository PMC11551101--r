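#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for report percentages so that
#' e.g. 15/24 sessions prints as 63% and 105/173 retention prints as 61%.
#' Base R's `round()` rounds half to even and would give different integers
#' on exact halves.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.5)   # 1, not 0
#' round_half_up(62.5)  # 63
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# GBP <-> integer pence. Sums are carried in pence so component totals are
# exact to the penny; conversion back to GBP happens only at reporting.
to_pence <- function(gbp) {
  out <- round_half_up(gbp * 100)
  storage.mode(out) <- "double" # keep > .Machine$integer.max safe
  out
}

from_pence <- function(pence) pence / 100

# stopifnot() with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

# Derive a stream-specific 31-bit seed from a user seed, so that independent
# stages (generation, dropout, imputation, chains) do not share streams.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647
}
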