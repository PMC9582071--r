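# internal helpers shared across modules

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding to the nearest integer, with exact halves moved away
#' from zero (so 103.5 -> 104, -2.5 -> -3). Used for display values of count
#' means, where `base::round()`'s round-half-to-even rule would be surprising.
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic per-component seed derived from one root seed, so that each
# generator component (codes, frequencies, names, ...) has its own stream and
# adding a component does not perturb the others. Stays below 2^31 - 1.
stream_seed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 1009393
  as.integer((abs(as.numeric(seed)) * 2017 + h) %% (.Machine$integer.max - 1)) + 1L
}
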