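#' Tidy a spectral estimate into a long tibble
#'
#' @param x A `spectral_estimate`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `freq`, `power_db`.
#' @export
tidy.spectral_estimate <- function(x, ...) {
  tibble::tibble(time = rep(x$times, times = length(x$freqs)),
                 freq = rep(x$freqs, each = length(x$times)),
                 power_db = as.numeric(x$power))
}

#' @export
glance.spectral_estimate <- function(x, ...) {
  tibble::tibble(n_windows = length(x$times), n_freqs = length(x$freqs),
                 fmin = min(x$freqs), fmax = max(x$freqs),
                 window_T = x$params$window_T, overlap = x$params$overlap,
                 TW = x$params$TW, K = x$params$K, fs = x$params$fs,
                 n_subjects = x$n_subjects)
}

#' Tidy a coherogram into a long tibble
#'
#' @param x A `coherogram`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `freq`, `coherence`.
#' @export
tidy.coherogram <- function(x, ...) {
  tibble::tibble(time = rep(x$times, times = length(x$freqs)),
                 freq = rep(x$freqs, each = length(x$times)),
                 coherence = as.numeric(x$coherence))
}

#' @export
glance.coherogram <- function(x, ...) {
  tibble::tibble(n_windows = length(x$times), n_freqs = length(x$freqs),
                 TW = x$params$TW, K = x$params$K,
                 n_subjects = x$n_subjects)
}

#' Tidy a global coherence spectrum
#'
#' @param x A `global_coherence`.
#' @param ... Unused.
#' @return Tibble with `freq`, `c_global`, `lambda_max`, `trace`.
#' @export
tidy.global_coherence <- function(x, ...) {
  tibble::tibble(freq = x$freqs, c_global = x$c_global,
                 lambda_max = x$eigenvalues[, 1],
                 trace = rowSums(x$eigenvalues))
}

#' @export
glance.global_coherence <- function(x, ...) {
  tibble::tibble(n_freqs = length(x$freqs),
                 n_channels = length(x$channels),
                 median_c_global = stats::median(x$c_global, na.rm = TRUE))
}

#' @export
glance.bootstrap_ci <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(n_freqs = nrow(x),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 n_replicates = cfg$n_replicates, ci_level = cfg$ci_level,
                 paired = cfg$paired,
                 n_A = attr(x, "n_A"), n_B = attr(x, "n_B"))
}

#' @export
glance.power_spectrum <- function(x, ...) {
  tibble::tibble(n_freqs = nrow(x), group = attr(x, "group"),
                 n_subjects = attr(x, "n_subjects"))
}
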