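#' Multitaper parameters for coherence estimation
#'
#' Coherence uses 2-s non-overlapping windows with TW = 3 and K = 5 tapers
#' (half-bandwidth W = 1.5 Hz), trading spectral resolution for the larger
#' taper count a stable single-window coherence estimate needs.
#'
#' @inheritParams multitaper_params
#' @return A `multitaper_params` object with coherence defaults.
#' @export
coherence_params <- function(window_T = 2, overlap = 0, TW = 3, K = 5,
                             fs = 256) {
  multitaper_params(window_T = window_T, overlap = overlap, TW = TW, K = K,
                    fs = fs)
}

# per-taper one-sided FFTs for a set of channels over non-overlapping
# windows: returns list over tapers of complex arrays (nf x n_windows x nch)
taper_fft_channels <- function(data, fs, params, fmax = NULL) {
  nwin <- round(params$window_T * fs)
  nw <- floor(nrow(data) / nwin)
  if (nw < 1) stop("epoch shorter than one window")
  tapers <- dpss_tapers(nwin, params$TW, params$K)
  nf <- floor(nwin / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / nwin
  if (!is.null(fmax)) {
    keep <- which(freqs <= fmax + 1e-9)
  } else keep <- seq_len(nf)
  nch <- ncol(data)
  out <- lapply(seq_len(params$K), function(k) {
    array(0i, dim = c(length(keep), nw, nch))
  })
  for (c in seq_len(nch)) {
    W <- matrix(data[seq_len(nw * nwin), c], nrow = nwin)
    W <- W - rep(colMeans(W), each = nwin)
    for (k in seq_len(params$K)) {
      F <- stats::mvfft(W * tapers[k, ])
      out[[k]][, , c] <- F[keep, , drop = FALSE]
    }
  }
  attr(out, "freqs") <- freqs[keep]
  attr(out, "n_windows") <- nw
  out
}

#' Pairwise multitaper coherogram
#'
#' Time-varying magnitude coherence between two channels:
#' C_ij(f, t) = |S_ij(f, t)| / sqrt(S_i(f, t) S_j(f, t)), with cross- and
#' auto-spectra estimated per non-overlapping window as means over the K
#' tapers. Values lie in \[0, 1\] by the Cauchy-Schwarz inequality; bins
#' where an auto-spectrum vanishes are undefined (NA).
#'
#' @param epoch An `eeg_epoch` (or samples x channels matrix with named
#'   columns plus `fs` via `params`).
#' @param chan_i,chan_j Channel labels (or indices).
#' @param params A [coherence_params()].
#' @param fmax Optional upper frequency bound for the returned grid.
#' @return A `coherogram`: list with `freqs`, `times`, `coherence`
#'   (time x frequency in \[0,1\]), `params`, `n_subjects`.
#' @export
pairwise_coherogram <- function(epoch, chan_i, chan_j,
                                params = coherence_params(), fmax = NULL) {
  data <- if (inherits(epoch, c("eeg_epoch", "eeg_recording"))) epoch$data
          else epoch
  fs <- if (inherits(epoch, c("eeg_epoch", "eeg_recording"))) epoch$fs
        else params$fs
  t0 <- (if (inherits(epoch, "eeg_epoch")) epoch$t_start else 0) %||% 0
  cols <- vapply(list(chan_i, chan_j), function(ch) {
    if (is.character(ch)) {
      j <- match(ch, colnames(data))
      if (is.na(j)) stop("channel not found: ", ch)
      j
    } else as.integer(ch)
  }, integer(1))
  ff <- taper_fft_channels(data[, cols, drop = FALSE], fs, params, fmax)
  Sij <- 0i; Sii <- 0; Sjj <- 0
  for (k in seq_along(ff)) {
    Xi <- ff[[k]][, , 1]; Xj <- ff[[k]][, , 2]
    Sij <- Sij + Xi * Conj(Xj)
    Sii <- Sii + Re(Xi)^2 + Im(Xi)^2
    Sjj <- Sjj + Re(Xj)^2 + Im(Xj)^2
  }
  denom <- sqrt(Sii * Sjj)
  coh <- Mod(Sij) / denom
  coh[denom == 0] <- NA_real_
  coh <- pmin(coh, 1)  # clamp rounding excess
  nwin <- round(params$window_T * fs)
  structure(list(freqs = attr(ff, "freqs"),
                 times = t0 + (seq_len(attr(ff, "n_windows")) - 1) *
                   nwin / fs + params$window_T / 2,
                 coherence = t(coh), params = params, n_subjects = 1L),
            class = "coherogram")
}

#' @export
print.coherogram <- function(x, ...) {
  cat("<coherogram> ", length(x$times), " windows x ", length(x$freqs),
      " freqs, n_subjects = ", x$n_subjects, "\n", sep = "")
  invisible(x)
}

#' Group-median coherogram
#'
#' Element-wise median across subjects at each time point and frequency.
#'
#' @param coherograms List of `coherogram`s on identical grids.
#' @return A `coherogram` with `n_subjects = length(coherograms)`.
#' @export
group_median_coherogram <- function(coherograms) {
  stopifnot(length(coherograms) >= 1)
  freqs <- check_common_grid(coherograms, "freqs")
  n_t <- vapply(coherograms, function(x) length(x$times), integer(1))
  if (length(unique(n_t)) != 1) stop("coherograms differ in window count")
  A <- vapply(coherograms, function(x) as.numeric(x$coherence),
              numeric(length(coherograms[[1]]$coherence)))
  structure(list(freqs = freqs, times = coherograms[[1]]$times,
                 coherence = matrix(matrixStats::rowMedians(A),
                                    nrow = n_t[1]),
                 params = coherograms[[1]]$params,
                 n_subjects = length(coherograms)),
            class = "coherogram")
}

#' Median-denoised cross-spectral matrix
#'
#' Divides the epoch into non-overlapping 2-s windows, estimates the
#' channels x channels cross-spectral matrix per window (mean over K
#' tapers), then denoises by taking the element-wise median of the real and
#' imaginary parts over consecutive blocks of `block` (default 10) windows.
#' Epochs longer than one block yield several independent block medians
#' whose mean is returned (a 5-min epoch gives 15 blocks). Hermitian
#' symmetry is enforced by construction.
#'
#' @param epoch An `eeg_epoch` (all channels used) or samples x channels
#'   matrix.
#' @param params A [coherence_params()].
#' @param block Windows per median block (epoch must contain at least one
#'   full block).
#' @param fmax Optional upper frequency bound.
#' @return A `cross_spectral_matrix`: list with `freqs`, `S` (complex array
#'   nf x N x N), `channels`, `n_windows`, `n_blocks`, `params`.
#' @export
cross_spectral_matrix <- function(epoch, params = coherence_params(),
                                  block = 10, fmax = NULL) {
  data <- if (inherits(epoch, c("eeg_epoch", "eeg_recording"))) epoch$data
          else epoch
  fs <- if (inherits(epoch, c("eeg_epoch", "eeg_recording"))) epoch$fs
        else params$fs
  nwin <- round(params$window_T * fs)
  nw <- floor(nrow(data) / nwin)
  if (nw < block) {
    stop("epoch has ", nw, " windows; at least ", block,
         " (", block * params$window_T, " s) required")
  }
  nch <- ncol(data)
  n_blocks <- floor(nw / block)
  tapers <- dpss_tapers(nwin, params$TW, params$K)
  nf_full <- floor(nwin / 2) + 1
  freqs <- (seq_len(nf_full) - 1) * fs / nwin
  keep <- if (is.null(fmax)) seq_len(nf_full) else
    which(freqs <= fmax + 1e-9)
  S <- cpp_csm(data, tapers, max(keep), as.integer(block))
  S <- S[keep, , , drop = FALSE]
  freqs <- freqs[keep]
  structure(list(freqs = freqs, S = S,
                 channels = colnames(data) %||% as.character(seq_len(nch)),
                 n_windows = nw, n_blocks = n_blocks, params = params),
            class = "cross_spectral_matrix")
}

#' @export
print.cross_spectral_matrix <- function(x, ...) {
  cat("<cross_spectral_matrix> ", length(x$channels), "x",
      length(x$channels), " over ", length(x$freqs), " freqs (",
      x$n_windows, " windows, ", x$n_blocks, " median blocks)\n", sep = "")
  invisible(x)
}

#' Global coherence spectrum
#'
#' Eigendecomposes the Hermitian cross-spectral matrix at each frequency,
#' S(f) = U(f) Lambda(f) U(f)^H, and returns the global coherence
#' C_global(f) = lambda_max(f) / sum_i lambda_i(f) together with the full
#' eigenvalue spectrum and the principal mode u_max (eigenvector of the
#' largest eigenvalue). Global coherence close to 1 means a single spatial
#' mode dominates all channels; for a diagonal (uncorrelated, equal-power)
#' matrix it equals 1/N.
#'
#' @param csm A [cross_spectral_matrix()].
#' @param psd_tol Relative tolerance for negative eigenvalues: values above
#'   `-psd_tol * trace` are clamped to zero, more negative matrices are
#'   rejected. Element-wise median denoising does not preserve positive
#'   semi-definiteness exactly, so mildly negative eigenvalues (well below
#'   1% of the trace in practice) are an expected artifact of the denoising
#'   step, not an error; the default 0.05 tolerates those while still
#'   rejecting genuinely indefinite input.
#' @return A `global_coherence` object: list with `freqs`, `c_global`
#'   (NA where the trace vanishes), `eigenvalues` (nf x N, decreasing,
#'   negatives clamped to 0), `u_max` (complex nf x N), `channels`.
#' @export
global_coherence <- function(csm, psd_tol = 0.05) {
  nf <- length(csm$freqs)
  N <- length(csm$channels)
  lam <- matrix(NA_real_, nf, N)
  umax <- matrix(NA_complex_, nf, N)
  cg <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    H <- csm$S[f, , ]
    e <- eigen(H, symmetric = TRUE)
    v <- e$values
    tr <- sum(v)
    if (any(v < -psd_tol * max(tr, .Machine$double.eps))) {
      stop("cross-spectral matrix at ", csm$freqs[f],
           " Hz is not positive semi-definite")
    }
    v[v < 0] <- 0
    lam[f, ] <- v
    umax[f, ] <- e$vectors[, 1]
    if (sum(v) > 0) cg[f] <- v[1] / sum(v)
  }
  structure(list(freqs = csm$freqs, c_global = cg, eigenvalues = lam,
                 u_max = umax, channels = csm$channels,
                 n_subjects = 1L),
            class = "global_coherence")
}

#' @export
print.global_coherence <- function(x, ...) {
  cat("<global_coherence> ", length(x$freqs), " freqs, ",
      length(x$channels), " channels; median c_global = ",
      signif(stats::median(x$c_global, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Spatial coherence map from the principal mode
#'
#' Per electrode, the squared magnitude of the principal-mode eigenvector
#' entry, |u_max|^2 (which sums to 1 over electrodes at each frequency),
#' averaged over each band's frequency bins.
#'
#' @param gcs A [global_coherence()] result.
#' @param scheme A [band_scheme()] tibble.
#' @return Tibble with `electrode` and one column per band.
#' @export
spatial_coherence_map <- function(gcs, scheme = band_scheme()) {
  U2 <- Mod(gcs$u_max)^2
  out <- tibble::tibble(electrode = gcs$channels)
  for (b in seq_len(nrow(scheme))) {
    bins <- band_bins(gcs$freqs, scheme$lo[b], scheme$hi[b], scheme$band[b])
    out[[scheme$band[b]]] <- if (length(bins) == 0) NA_real_ else
      colMeans(U2[bins, , drop = FALSE])
  }
  out
}
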