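#' Bootstrap configuration
#'
#' @param n_replicates Number of bootstrap replicates (2000 for reported
#'   runs; at least 100).
#' @param ci_level Confidence level in percent, in (0, 100).
#' @param paired Paired comparison (within-subject differences) or unpaired
#'   (independent groups).
#' @param seed Integer seed; the whole resampling stream derives from it.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_replicates = 2000, ci_level = 95,
                             paired = FALSE, seed = 1L) {
  if (n_replicates < 100) stop("n_replicates must be at least 100")
  if (ci_level <= 0 || ci_level >= 100) stop("ci_level must be in (0, 100)")
  structure(list(n_replicates = as.integer(n_replicates),
                 ci_level = ci_level, paired = isTRUE(paired),
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Per-subject mean spectrum for resampling
#'
#' Collapses a single-subject spectrogram to its time-mean spectrum in
#' linear power and records the estimate's degrees of freedom
#' m = K x n_windows, which sets the sampling variance of bootstrap
#' replicates.
#'
#' @param estimate A single-subject `spectral_estimate`.
#' @return A `subject_spectrum` tibble with columns `freq`, `power`
#'   (uV^2/Hz, linear); attribute `m`.
#' @export
subject_mean_spectrum <- function(estimate) {
  stopifnot(inherits(estimate, "spectral_estimate"))
  out <- tibble::tibble(freq = estimate$freqs,
                        power = colMeans(from_db(estimate$power)))
  attr(out, "m") <- estimate$params$K *
    (estimate$n_windows %||% length(estimate$times))
  class(out) <- c("subject_spectrum", class(out))
  out
}

#' One frequency-domain bootstrap replicate of a subject spectrum
#'
#' The replicate at each frequency is distributed as the mean of m squared
#' complex Fourier coefficients whose real and imaginary parts are
#' independent Normal(0, S(f)/2) — i.e. exactly Gamma(shape = m,
#' scale = S(f)/m), with expectation S(f). The Gamma draw is used directly;
#' it is the same law as averaging the m coefficient draws.
#'
#' @param subject_spectrum A [subject_mean_spectrum()] (or tibble with
#'   `freq`, `power`).
#' @param seed Optional seed making the replicate reproducible.
#' @param m Degrees of freedom; defaults to the spectrum's `m` attribute.
#' @return A `subject_spectrum` replicate on the same grid.
#' @export
resample_subject_spectrum <- function(subject_spectrum, seed = NULL,
                                      m = attr(subject_spectrum, "m")) {
  S <- subject_spectrum$power
  if (any(S < 0)) stop("spectral power must be non-negative")
  if (is.null(m)) stop("degrees of freedom m not provided")
  draw <- function() {
    r <- numeric(length(S))
    pos <- S > 0
    r[pos] <- stats::rgamma(sum(pos), shape = m, rate = m / S[pos])
    r
  }
  r <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- tibble::tibble(freq = subject_spectrum$freq, power = r)
  attr(out, "m") <- m
  class(out) <- c("subject_spectrum", class(out))
  out
}

# draws an (n_subjects x nf x R) array of replicate powers in one call;
# P: nf x n_subjects linear power, m: per-subject dof vector
draw_replicates <- function(P, m, R) {
  nf <- nrow(P); ns <- ncol(P)
  shape <- rep(rep(m, each = nf), times = R)
  mean_ <- rep(as.numeric(P), times = R)
  out <- numeric(length(mean_))
  pos <- mean_ > 0
  out[pos] <- stats::rgamma(sum(pos), shape = shape[pos],
                            rate = shape[pos] / mean_[pos])
  array(out, dim = c(nf, ns, R))
}

# per-replicate cross-subject medians in dB: input array (nf, ns, R)
replicate_medians_db <- function(A) {
  d <- dim(A)
  M <- matrix(aperm(A, c(2, 1, 3)), nrow = d[2])  # ns x (nf*R)
  matrix(to_db(matrixStats::colMedians(M)), nrow = d[1])  # nf x R
}

#' Frequency-domain bootstrap CI for a group spectral difference
#'
#' For each replicate, every subject's spectrum is resampled (see
#' [resample_subject_spectrum()]), cross-subject medians are taken per
#' group in dB, and the difference A - B is formed per frequency. In the
#' paired variant the median of within-subject dB differences is used. The
#' confidence envelope is the percentile interval of the replicate
#' differences (linear-interpolation percentiles); a frequency is flagged
#' significant when its interval excludes 0. No multiple-comparison
#' correction is applied, mirroring per-frequency CI bands.
#'
#' @param spectra_A,spectra_B Lists of [subject_mean_spectrum()] objects on
#'   a common frequency grid (equal-length, subject-matched lists when
#'   `config$paired`).
#' @param config A [bootstrap_config()].
#' @return A `bootstrap_ci` tibble: `freq`, `observed_db`, `lower_db`,
#'   `upper_db`, `significant`; attributes `config`, `n_A`, `n_B`.
#' @export
bootstrap_group_difference <- function(spectra_A, spectra_B,
                                       config = bootstrap_config()) {
  if (config$paired && length(spectra_A) != length(spectra_B)) {
    stop("paired comparison requires equal-length, subject-matched lists")
  }
  if (!config$paired && (length(spectra_A) < 2 || length(spectra_B) < 2)) {
    stop("unpaired comparison requires at least 2 subjects per group")
  }
  freqs <- check_common_grid(c(spectra_A, spectra_B), "freq")
  PA <- vapply(spectra_A, function(s) s$power, numeric(length(freqs)))
  PB <- vapply(spectra_B, function(s) s$power, numeric(length(freqs)))
  mA <- vapply(spectra_A, function(s) attr(s, "m") %||%
                 stop("subject spectrum lacks m"), numeric(1))
  mB <- vapply(spectra_B, function(s) attr(s, "m") %||%
                 stop("subject spectrum lacks m"), numeric(1))
  R <- config$n_replicates
  obs_diff <- observed_difference_db(PA, PB, config$paired)
  diffs <- withr::with_seed(config$seed, {
    RA <- draw_replicates(PA, mA, R)
    RB <- draw_replicates(PB, mB, R)
    if (config$paired) {
      D <- to_db(RA) - to_db(RB)          # nf x ns x R
      d <- dim(D)
      M <- matrix(aperm(D, c(2, 1, 3)), nrow = d[2])
      matrix(matrixStats::colMedians(M), nrow = d[1])
    } else {
      replicate_medians_db(RA) - replicate_medians_db(RB)
    }
  })
  alpha <- (100 - config$ci_level) / 200
  qs <- matrixStats::rowQuantiles(diffs, probs = c(alpha, 1 - alpha),
                                  type = 7L)
  out <- tibble::tibble(freq = freqs,
                        observed_db = obs_diff,
                        lower_db = qs[, 1],
                        upper_db = qs[, 2],
                        significant = qs[, 1] > 0 | qs[, 2] < 0)
  attr(out, "config") <- config
  attr(out, "n_A") <- length(spectra_A)
  attr(out, "n_B") <- length(spectra_B)
  class(out) <- c("bootstrap_ci", class(out))
  out
}

observed_difference_db <- function(PA, PB, paired) {
  if (paired) {
    matrixStats::rowMedians(to_db(PA) - to_db(PB))
  } else {
    to_db(matrixStats::rowMedians(PA)) - to_db(matrixStats::rowMedians(PB))
  }
}

#' Fraction of significant frequencies per band
#'
#' Band-level summary of a [bootstrap_group_difference()] result: the
#' fraction of the band's frequency bins whose CI excludes zero.
#'
#' @param result A `bootstrap_ci`.
#' @param scheme A [band_scheme()].
#' @return Tibble with `band`, `n_bins`, `frac_significant`.
#' @export
band_significance <- function(result, scheme = band_scheme()) {
  purrr::map_dfr(seq_len(nrow(scheme)), function(b) {
    bins <- band_bins(result$freq, scheme$lo[b], scheme$hi[b],
                      scheme$band[b])
    tibble::tibble(band = scheme$band[b], n_bins = length(bins),
                   frac_significant = if (length(bins) > 0)
                     mean(result$significant[bins]) else NA_real_)
  })
}

#' Paired bootstrap: MOSSA versus first-movement spectra
#'
#' Computes per-subject mean spectra (multitaper module) for each subject's
#' pre-gas-off MOSSA epoch and post-movement epoch, then runs the paired
#' frequency-domain bootstrap on the within-subject differences. Subjects
#' missing either epoch are dropped with a message.
#'
#' @param subject_epoch_pairs List of lists with elements `mossa` and
#'   `movement` (each an `eeg_epoch` or NULL).
#' @param config A [bootstrap_config()] (forced paired).
#' @param params A [multitaper_params()] for the spectra.
#' @param channel Channel analyzed (default F7).
#' @param fmax Upper frequency bound of the comparison grid.
#' @return A `bootstrap_ci` (MOSSA minus movement, dB).
#' @export
mossa_vs_movement_difference <- function(subject_epoch_pairs,
                                         config = bootstrap_config(paired = TRUE),
                                         params = multitaper_params(),
                                         channel = "F7", fmax = 30) {
  config$paired <- TRUE
  keep <- purrr::keep(subject_epoch_pairs, function(p) {
    ok <- !is.null(p$mossa) && !is.null(p$movement)
    if (!ok) message("dropping subject with missing MOSSA/movement epoch")
    ok
  })
  if (length(keep) == 0) stop("no subjects with both epochs")
  spec_of <- function(ep) {
    subject_mean_spectrum(multitaper_spectrogram(ep, params,
                                                 channel = channel,
                                                 fmax = fmax))
  }
  spectra_m <- purrr::map(keep, function(p) spec_of(p$mossa))
  spectra_v <- purrr::map(keep, function(p) spec_of(p$movement))
  bootstrap_group_difference(spectra_m, spectra_v, config)
}
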