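#' Multitaper estimation parameters
#'
#' Container for the multitaper settings used by [multitaper_spectrogram()].
#' Defaults are the spectral-analysis settings used throughout the package
#' for power: 2-s windows with 1.9-s overlap, time-bandwidth product TW = 2
#' and K = 3 tapers, giving a spectral half-bandwidth W = TW/T = 1 Hz.
#'
#' @param window_T Window length in seconds.
#' @param overlap Window overlap in seconds (must be < `window_T`).
#' @param TW Time-bandwidth product (dimensionless).
#' @param K Number of DPSS tapers; must satisfy K <= 2*TW - 1.
#' @param fs Sampling rate in Hz.
#' @return A `multitaper_params` list.
#' @export
multitaper_params <- function(window_T = 2, overlap = 1.9, TW = 2, K = 3,
                              fs = 256) {
  stopifnot(window_T > 0, fs > 0)
  if (overlap >= window_T) stop("overlap must be smaller than window_T")
  if (K > 2 * TW - 1) stop("K must satisfy K <= 2*TW - 1 (got K=", K,
                           ", TW=", TW, ")")
  if (K < 1) stop("K must be >= 1")
  structure(list(window_T = window_T, overlap = overlap, TW = TW, K = K,
                 fs = fs),
            class = "multitaper_params")
}

#' Frequency-band scheme
#'
#' The five reporting bands: slow 0.1-1 Hz, delta 1-4 Hz, theta 4-8 Hz,
#' alpha 8-12 Hz, beta 12-30 Hz. Bands are contiguous; on a discrete
#' frequency grid a bin at frequency f belongs to the band with
#' lo < f <= hi, except the slow band which spans 0.1 to 1 Hz inclusive (so with a
#' 0.5-Hz grid it holds the 0.5 and 1.0 Hz bins; DC is never included).
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
band_scheme <- function() {
  tibble::tibble(
    band = c("slow", "delta", "theta", "alpha", "beta"),
    lo = c(0.1, 1, 4, 8, 12),
    hi = c(1, 4, 8, 12, 30)
  )
}

# indices of grid frequencies belonging to a band (see band_scheme docs)
band_bins <- function(freqs, lo, hi, band = NULL) {
  if (!is.null(band) && identical(band, "slow")) {
    which(freqs >= lo - 1e-9 & freqs <= hi + 1e-9 & freqs > 0)
  } else {
    which(freqs > lo + 1e-9 & freqs <= hi + 1e-9)
  }
}

# cache for DPSS computations (keyed by n/TW/K)
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `K` DPSS tapers of length `n_samples` for
#' time-bandwidth product `TW`, via the classical symmetric-tridiagonal
#' eigenproblem whose eigenvectors are the Slepian sequences. Tapers are
#' orthonormal (unit energy) and ordered by decreasing spectral
#' concentration in the band -W..W, W = TW/n_samples cycles/sample.
#' Sign convention: symmetric tapers have positive mean; antisymmetric
#' tapers have a positive leading element.
#'
#' @param n_samples Taper length in samples.
#' @param TW Time-bandwidth product; K must satisfy K <= 2*TW - 1.
#' @param K Number of tapers.
#' @return K x n_samples matrix, one taper per row.
#' @export
dpss_tapers <- function(n_samples, TW, K) {
  if (K > 2 * TW - 1) stop("K must satisfy K <= 2*TW - 1 (got K=", K,
                           ", TW=", TW, ")")
  if (n_samples < K) stop("n_samples must be >= K")
  key <- paste(n_samples, TW, K, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- n_samples
  w <- TW / n
  t <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- (t * (n - t) / 2)[2:n]
  Tm <- matrix(0, n, n)
  diag(Tm) <- dg
  Tm[cbind(1:(n - 1), 2:n)] <- od
  Tm[cbind(2:n, 1:(n - 1))] <- od
  e <- eigen(Tm, symmetric = TRUE)
  V <- e$vectors[, seq_len(K), drop = FALSE]  # eigen returns decreasing order
  for (k in seq_len(K)) {
    v <- V[, k]
    s <- sum(v)
    flip <- if (abs(s) > 1e-8) s < 0 else v[2] < v[1]
    if (isTRUE(flip)) V[, k] <- -v
  }
  out <- t(V)
  .dpss_cache[[key]] <- out
  out
}

# Tapered FFTs of a set of windows.
# x: numeric vector; starts: 0-based start samples; nwin samples per window.
# Returns a list with one (nfft x n_windows) complex matrix per taper.
# Windows are demeaned before tapering (drift control).
tapered_ffts <- function(x, starts, nwin, tapers) {
  idx <- outer(seq_len(nwin), starts, `+`)  # nwin x n_windows
  Xw <- matrix(x[idx], nrow = nwin)
  Xw <- sweep(Xw, 2, colMeans(Xw))
  lapply(seq_len(nrow(tapers)), function(k) {
    stats::mvfft(Xw * tapers[k, ])
  })
}

# start samples (0-based) for spectrogram windows over n samples at fs
spectrogram_starts <- function(n_samples, params) {
  nwin <- round(params$window_T * params$fs)
  step_s <- params$window_T - params$overlap
  st <- window_starts(n_samples / params$fs, params$window_T, step_s)
  starts <- round(st * params$fs)
  starts[starts + nwin <= n_samples]
}

#' Multitaper spectrogram of one channel
#'
#' Slides DPSS-tapered windows along a single-channel epoch and estimates
#' power spectral density per window as the mean over `K` tapered
#' periodograms. The FFT length equals the window length in samples (no
#' zero padding), so at 256 Hz with T = 2 s the grid spacing is 0.5 Hz.
#' One-sided densities in uV^2/Hz; the returned `power` is in dB
#' (10*log10), with -Inf where the windowed signal is identically zero.
#'
#' @param epoch An `eeg_epoch` (see [extract_state_epochs()]) or a numeric
#'   vector (then `fs` is taken from `params`).
#' @param params A [multitaper_params()].
#' @param channel Channel label or index when `epoch` is multichannel.
#' @param fmax Keep only frequencies <= `fmax` Hz (NULL = full one-sided grid).
#' @return A `spectral_estimate`: list with `freqs` (Hz), `times` (s, window
#'   centers, absolute if the epoch carries `t_start`), `power`
#'   (time x frequency, dB), `params`, `n_subjects = 1`.
#' @export
multitaper_spectrogram <- function(epoch, params = multitaper_params(),
                                   channel = NULL, fmax = NULL) {
  x <- epoch_channel(epoch, channel)
  fs <- attr(x, "fs") %||% params$fs
  t0 <- attr(x, "t_start") %||% 0
  params$fs <- fs
  nwin <- round(params$window_T * fs)
  if (length(x) < nwin) stop("epoch shorter than one window")
  starts <- spectrogram_starts(length(x), params)
  tapers <- dpss_tapers(nwin, params$TW, params$K)
  nf_full <- floor(nwin / 2) + 1
  freqs <- (seq_len(nf_full) - 1) * fs / nwin
  nf <- if (is.null(fmax)) nf_full else
    max(which(freqs <= fmax + 1e-9))
  freqs <- freqs[seq_len(nf)]
  pow <- cpp_mt_power(as.numeric(x), starts, tapers, nf) / fs
  # one-sided: double all bins except DC and (for even nwin) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nwin %% 2 == 0 && nf == nf_full) dbl[nf] <- 1
  pow <- pow * dbl
  new_spectral_estimate(
    freqs = freqs,
    times = t0 + starts / fs + params$window_T / 2,
    power = t(to_db(pow)),
    params = params,
    n_subjects = 1L,
    n_windows = length(starts)
  )
}

new_spectral_estimate <- function(freqs, times, power, params, n_subjects,
                                  n_windows = NA_integer_) {
  structure(list(freqs = freqs, times = times, power = power,
                 params = params, n_subjects = n_subjects,
                 n_windows = n_windows),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("<spectral_estimate> ", length(x$times), " windows x ",
      length(x$freqs), " freqs (", min(x$freqs), "-", max(x$freqs),
      " Hz), n_subjects = ", x$n_subjects, "\n", sep = "")
  invisible(x)
}

# extract one channel as a numeric vector carrying fs/t_start attributes
epoch_channel <- function(epoch, channel = NULL) {
  if (is.numeric(epoch) && is.null(dim(epoch))) return(epoch)
  data <- if (inherits(epoch, c("eeg_epoch", "eeg_recording"))) epoch$data
          else epoch
  if (is.null(channel)) {
    if (ncol(data) != 1) stop("multichannel input: specify `channel`")
    channel <- 1L
  }
  if (is.character(channel)) {
    j <- match(channel, colnames(data))
    if (is.na(j)) stop("channel not found: ", channel)
  } else j <- channel
  x <- data[, j]
  if (inherits(epoch, c("eeg_epoch", "eeg_recording"))) {
    attr(x, "fs") <- epoch$fs
    attr(x, "t_start") <- epoch$t_start %||% 0
  }
  x
}

check_common_grid <- function(estimates, what = "freqs") {
  ref <- estimates[[1]][[what]]
  for (e in estimates[-1]) {
    if (length(e[[what]]) != length(ref) ||
        max(abs(e[[what]] - ref)) > 1e-9) {
      stop("estimates are not on a common ", what, " grid")
    }
  }
  ref
}

#' Group-median spectrogram
#'
#' Element-wise median across subjects at each time and frequency, computed
#' in dB (the package's convention for group summaries of log power).
#'
#' @param estimates List of `spectral_estimate`s on identical time/frequency
#'   grids.
#' @return A `spectral_estimate` with `n_subjects = length(estimates)`.
#' @export
group_median_spectrogram <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  freqs <- check_common_grid(estimates, "freqs")
  times <- check_common_grid(estimates, "times")
  A <- vapply(estimates, function(e) as.numeric(e$power),
              numeric(length(estimates[[1]]$power)))
  med <- matrixStats::rowMedians(A)
  new_spectral_estimate(
    freqs = freqs, times = times,
    power = matrix(med, nrow = length(times)),
    params = estimates[[1]]$params,
    n_subjects = length(estimates)
  )
}

#' Group-median power spectrum with IQR envelope
#'
#' For each subject the spectrogram is first averaged over time (in linear
#' power, then converted to dB), then the cross-subject median and 25th/75th
#' percentiles are taken per frequency (linear-interpolation percentiles).
#'
#' @param estimates List of single-subject `spectral_estimate`s on a common
#'   frequency grid.
#' @param group Label describing the group (stored on the result).
#' @return A `power_spectrum` tibble with columns `freq`, `median_db`,
#'   `p25_db`, `p75_db`; attributes `group`, `n_subjects`, and `m` (per
#'   subject degrees of freedom, K x n_windows, used by the bootstrap).
#' @export
group_spectrum <- function(estimates, group = NA_character_) {
  stopifnot(length(estimates) >= 1)
  freqs <- check_common_grid(estimates, "freqs")
  means_db <- vapply(estimates, function(e) subject_mean_spectrum_db(e),
                     numeric(length(freqs)))
  qs <- matrixStats::rowQuantiles(means_db, probs = c(0.25, 0.5, 0.75),
                                  type = 7L)
  out <- tibble::tibble(freq = freqs,
                        median_db = qs[, 2],
                        p25_db = qs[, 1],
                        p75_db = qs[, 3])
  attr(out, "group") <- group
  attr(out, "n_subjects") <- length(estimates)
  attr(out, "m") <- vapply(estimates,
                           function(e) e$params$K *
                             (e$n_windows %||% length(e$times)),
                           numeric(1))
  class(out) <- c("power_spectrum", class(out))
  out
}

# time-mean of a single-subject spectrogram, in dB
subject_mean_spectrum_db <- function(estimate) {
  to_db(colMeans(from_db(estimate$power)))
}

#' Band-power topography table
#'
#' Mean over each band's frequency bins of the per-electrode group-median
#' spectrum (time-mean of the group-median spectrogram), yielding an
#' electrode x band table of dB power suitable for scalp interpolation.
#'
#' @param per_electrode_estimates Named list (electrode label ->
#'   `spectral_estimate`, typically a group-median spectrogram).
#' @param scheme A [band_scheme()] tibble.
#' @return Tibble with columns `electrode`, one column per band (dB);
#'   electrodes with a missing estimate get NA in every band.
#' @export
band_power_topography <- function(per_electrode_estimates,
                                  scheme = band_scheme()) {
  stopifnot(length(per_electrode_estimates) >= 1)
  labs <- names(per_electrode_estimates)
  if (is.null(labs)) stop("per_electrode_estimates must be a named list")
  rows <- purrr::map(labs, function(lab) {
    e <- per_electrode_estimates[[lab]]
    vals <- stats::setNames(rep(NA_real_, nrow(scheme)), scheme$band)
    if (!is.null(e)) {
      spec_db <- subject_mean_spectrum_db(e)
      for (b in seq_len(nrow(scheme))) {
        bins <- band_bins(e$freqs, scheme$lo[b], scheme$hi[b], scheme$band[b])
        if (length(bins) == 0) {
          stop("band '", scheme$band[b],
               "' has no bins on the frequency grid")
        }
        vals[b] <- mean(spec_db[bins])
      }
    }
    dplyr::bind_cols(tibble::tibble(electrode = lab),
                     tibble::as_tibble(as.list(vals)))
  })
  dplyr::bind_rows(rows)
}
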