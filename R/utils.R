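#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom Rcpp evalCpp
#' @useDynLib sevoeeg, .registration = TRUE
NULL

#' @export
generics::tidy

#' @export
generics::glance

# dB conversions (power quantities)
to_db <- function(p) 10 * log10(p)
from_db <- function(db) 10^(db / 10)

# window start times for a sliding window of length win_s stepping by step_s
# over a duration dur_s, robust to floating-point (floor((dur-win)/step)+1
# windows). Times are seconds relative to the start of the segment.
window_starts <- function(dur_s, win_s, step_s) {
  n <- floor((dur_s - win_s) / step_s + 1e-9) + 1
  if (n < 1) return(numeric(0))
  (seq_len(n) - 1) * step_s
}

# derive a child seed from a parent seed; keeps results within 32-bit range
derive_seed <- function(seed, k) {
  (as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647
}
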