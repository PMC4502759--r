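#' Nearest-neighbor surface-Laplacian weights
#'
#' For each non-excluded electrode, neighbor weights are inverse great-circle
#' distance, normalized to sum to 1: w_ij = (1/d_ij) / sum_k (1/d_ik), with
#' d the great-circle distance on the unit sphere (the stand-in for distance
#' along the scalp surface). Neighbor sets come from the montage adjacency.
#'
#' @param montage An `eeg_montage`.
#' @return A `laplacian_weights` object: named list electrode -> named
#'   numeric vector of neighbor weights; attribute `matrix` holds the dense
#'   weight matrix W (rows sum to 1) over analyzable channels.
#' @export
build_laplacian_weights <- function(montage) {
  labs <- montage_channels(montage)
  D <- montage_distances(montage, labs)
  W <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  wl <- stats::setNames(vector("list", length(labs)), labs)
  for (lab in labs) {
    nb <- montage$adjacency[[lab]]
    if (length(nb) == 0) stop("electrode ", lab, " has no neighbors")
    inv <- 1 / D[lab, nb]
    w <- inv / sum(inv)
    wl[[lab]] <- w
    W[lab, nb] <- w
  }
  structure(wl, class = "laplacian_weights", matrix = W)
}

#' Apply the surface-Laplacian re-reference
#'
#' Each analyzable channel becomes itself minus the distance-weighted mean
#' of its neighbors; excluded electrodes are dropped from the output.
#' A spatially uniform signal maps exactly to zero.
#'
#' @param recording An `eeg_recording` (or `eeg_epoch`).
#' @param weights A [build_laplacian_weights()] object.
#' @return The re-referenced recording, channels reduced to the analyzable
#'   set.
#' @export
apply_laplacian <- function(recording, weights) {
  W <- attr(weights, "matrix")
  labs <- rownames(W)
  missing <- setdiff(labs, colnames(recording$data))
  if (length(missing) > 0) {
    stop("recording is missing channel(s): ", paste(missing, collapse = ", "))
  }
  X <- recording$data[, labs, drop = FALSE]
  L <- diag(length(labs)) - W
  out <- X %*% t(L)
  colnames(out) <- labs
  recording$data <- out
  recording$channels <- labs
  recording
}

# blackman-window FIR low-pass, odd length, unity DC gain, -6 dB at cutoff
design_antialias_fir <- function(fs, cutoff_hz, n_taps) {
  h <- signal::fir1(n_taps - 1, cutoff_hz / (fs / 2), type = "low",
                    window = signal::blackman(n_taps))
  h / sum(h)
}

#' Anti-alias filter and downsample to the analysis rate
#'
#' Zero-phase FIR low-pass (Blackman-window design, -6 dB at the cutoff,
#' stop-band attenuation beyond 60 dB well before the output Nyquist)
#' followed by integer decimation. A 256-Hz input passes through with
#' filtering only. The input is reflect-padded so DC is preserved exactly.
#'
#' @param recording An `eeg_recording`.
#' @param cutoff_hz Anti-alias cutoff (Hz).
#' @param target_fs Output sampling rate (Hz); the input rate must be an
#'   integer multiple of it.
#' @param n_taps Filter length (odd). Defaults to 129 when decimating from
#'   1024 Hz and 65 otherwise, both comfortably inside the attenuation
#'   targets.
#' @return The filtered, downsampled recording.
#' @export
antialias_downsample <- function(recording, cutoff_hz = 80, target_fs = 256,
                                 n_taps = NULL) {
  fs <- recording$fs
  if (abs(fs / target_fs - round(fs / target_fs)) > 1e-9) {
    stop("input rate ", fs, " Hz is not an integer multiple of ", target_fs,
         " Hz")
  }
  q <- round(fs / target_fs)
  if (is.null(n_taps)) n_taps <- if (q > 1) 129L else 65L
  if (n_taps %% 2 == 0) stop("n_taps must be odd (zero-phase symmetric FIR)")
  h <- design_antialias_fir(fs, cutoff_hz, n_taps)
  recording$data <- cpp_fir_decimate(recording$data, h, as.integer(q))
  colnames(recording$data) <- recording$channels
  recording$fs <- target_fs
  recording
}

#' Per-sample artifact mask
#'
#' Flags samples whose absolute amplitude exceeds the threshold on any
#' channel (an automated surrogate for visual artifact screening). An epoch
#' with more than 10% flagged samples is marked rejected.
#'
#' @param epoch An `eeg_epoch` or `eeg_recording`.
#' @param amplitude_threshold_uv Threshold in microvolts (> 0).
#' @return Logical vector, one element per sample; attribute `rejected`
#'   is TRUE when more than 10% of samples are flagged.
#' @export
artifact_mask <- function(epoch, amplitude_threshold_uv = 200) {
  stopifnot(amplitude_threshold_uv > 0)
  mask <- matrixStats::rowMaxs(abs(epoch$data)) > amplitude_threshold_uv
  attr(mask, "rejected") <- mean(mask) > 0.10
  mask
}

new_epoch <- function(recording, t_start, duration, state,
                      etsevo_bin = NA_integer_) {
  i0 <- round(t_start * recording$fs) + 1
  i1 <- i0 + round(duration * recording$fs) - 1
  if (i0 < 1 || i1 > nrow(recording$data)) {
    stop("epoch [", t_start, ", ", t_start + duration,
         ") s lies outside the recording")
  }
  structure(list(data = recording$data[i0:i1, , drop = FALSE],
                 fs = recording$fs, t_start = t_start,
                 duration = duration, state = state,
                 etsevo_bin = etsevo_bin,
                 subject_id = recording$subject_id,
                 age_group = recording$age_group),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat("<eeg_epoch> ", x$subject_id %||% "?", " ", x$state, " [",
      x$t_start, ", ", x$t_start + x$duration, ") s, ",
      ncol(x$data), " ch @ ", x$fs, " Hz",
      if (!is.na(x$etsevo_bin)) paste0(", etSEVO bin ", x$etsevo_bin) else "",
      "\n", sep = "")
  invisible(x)
}

# first t (1-s grid) in [t_lo, t_hi - dur] where the epoch passes the
# artifact rule; NA if none
first_clean_start <- function(recording, t_lo, t_hi, dur, threshold) {
  starts <- seq(ceiling(t_lo), floor(t_hi - dur))
  for (t in starts) {
    ep <- new_epoch(recording, t, dur, "candidate")
    if (!attr(artifact_mask(ep, threshold), "rejected")) return(t)
  }
  NA_real_
}

# time at which gas is turned off: one second past the last increase of the
# concentration trace (the plateau jitters both ways; emergence is the final
# monotone decay)
gas_off_time <- function(sevo) {
  inc <- which(diff(sevo$concentration) > 1e-9)
  if (length(inc) == 0) return(sevo$time[1])
  sevo$time[max(inc) + 1]
}

#' Extract state-specific analysis epochs
#'
#' Implements the epoch rules applied per state:
#' * `"MOSSA"`: one 300-s epoch centered in the first 600-s window of the
#'   concentration trace whose samples stay within 0.1% of the window median
#'   (and whose median exceeds 0.2%, i.e. gas actually on).
#' * `"awake"`: one 11-s artifact-free epoch inside the pre-induction
#'   segment (times before the concentration first rises above 0).
#' * `"first_movement"`: two epochs — a 20-s MOSSA epoch starting 600 s
#'   before gas-off, and a post-movement epoch of up to 30 s (at least 5 s)
#'   starting at the first gross body movement, within 120 s of it.
#'
#' When no qualifying window exists the state yields no epochs and a message
#' records the exclusion, mirroring how unusable epochs are dropped rather
#' than imputed.
#'
#' @param recording An `eeg_recording` (analysis rate).
#' @param sevo The subject's `sevo_trace`.
#' @param annotations Movement annotation tibble (needs `t_first_movement`
#'   for `state = "first_movement"`).
#' @param state One of `"MOSSA"`, `"awake"`, `"first_movement"`.
#' @param artifact_threshold_uv Amplitude threshold for the artifact rule.
#' @return List of `eeg_epoch` objects (possibly empty).
#' @export
extract_state_epochs <- function(recording, sevo, annotations = NULL,
                                 state = c("MOSSA", "awake",
                                           "first_movement"),
                                 artifact_threshold_uv = 200) {
  state <- match.arg(state)
  dur_rec <- nrow(recording$data) / recording$fs
  drop_msg <- function(why) {
    message("subject ", recording$subject_id %||% "?", ", state ", state,
            ": no qualifying epoch (", why, ")")
    list()
  }
  if (state == "MOSSA") {
    w <- find_stable_window(sevo, window_s = 600, tol = 0.1, min_conc = 0.2)
    if (is.na(w)) return(drop_msg("no 600-s constant-concentration window"))
    t0 <- first_clean_start(recording, w + 150, w + 450 + 1e-9, 300,
                            artifact_threshold_uv)
    if (is.na(t0)) t0 <- w + 150  # fall back to the centered epoch
    if (t0 + 300 > dur_rec) return(drop_msg("window exceeds recording"))
    return(list(new_epoch(recording, t0, 300, "MOSSA")))
  }
  if (state == "awake") {
    on_idx <- which(sevo$concentration > 1e-9)
    t_ind <- if (length(on_idx) == 0) dur_rec else sevo$time[on_idx[1]]
    if (t_ind < 11) return(drop_msg("no awake segment of 11 s"))
    t0 <- first_clean_start(recording, 0, t_ind, 11, artifact_threshold_uv)
    if (is.na(t0)) return(drop_msg("no artifact-free 11-s awake window"))
    return(list(new_epoch(recording, t0, 11, "awake")))
  }
  # first_movement: paired pre-gas-off MOSSA and post-movement epochs
  if (is.null(annotations) || nrow(annotations) == 0 ||
      is.na(annotations$t_first_movement[1])) {
    return(drop_msg("no movement annotation"))
  }
  t_gas_off <- gas_off_time(sevo)
  out <- list()
  t_pre <- t_gas_off - 600
  if (t_pre >= 0 && t_pre + 20 <= dur_rec) {
    out <- c(out, list(new_epoch(recording, t_pre, 20, "MOSSA")))
  } else {
    message("subject ", recording$subject_id %||% "?",
            ": pre-gas-off MOSSA epoch outside recording")
  }
  t_mv <- annotations$t_first_movement[1]
  dur_mv <- min(30, dur_rec - t_mv, 120)
  if (dur_mv >= 5) {
    out <- c(out, list(new_epoch(recording, t_mv, dur_mv, "first_movement")))
  } else {
    message("subject ", recording$subject_id %||% "?",
            ": fewer than 5 s available after first movement")
  }
  out
}

# start time of the first window_s-long window of the trace whose samples
# all lie within tol of the window median (and median > min_conc); NA if none
find_stable_window <- function(sevo, window_s = 600, tol = 0.1,
                               min_conc = 0.2) {
  tt <- sevo$time; cc <- sevo$concentration
  n <- length(tt)
  for (i in seq_len(n)) {
    j <- i + window_s - 1
    if (j > n) break
    win <- cc[i:j]
    med <- stats::median(win)
    if (med > min_conc && max(abs(win - med)) <= tol + 1e-9) return(tt[i])
  }
  NA_real_
}

#' End-tidal sevoflurane concentration bins
#'
#' @return Tibble with `bin` (1-10), `lo`, `hi`; bin b covers
#'   \[0.3(b-1), 0.3b) percent.
#' @export
etsevo_bins <- function() {
  tibble::tibble(bin = 1:10, lo = 0.3 * (0:9), hi = 0.3 * (1:10))
}

#' Emergence epochs binned by end-tidal concentration
#'
#' For each of the 10 end-tidal sevoflurane concentration ranges
#' (\[0, 0.3), \[0.3, 0.6), ..., \[2.7, 3.0) percent) extracts at most one
#' artifact-free epoch whose samples all fall at times when the
#' concentration lies inside the bin: 30 s preferred, falling back to 20 s
#' then 15 s. Missing bins are allowed.
#'
#' @param recording An `eeg_recording` (analysis rate).
#' @param sevo The subject's `sevo_trace`.
#' @param artifact_threshold_uv Amplitude threshold for the artifact rule.
#' @return List of `eeg_epoch`s with `etsevo_bin` set.
#' @export
bin_emergence_epochs <- function(recording, sevo,
                                 artifact_threshold_uv = 200) {
  bins <- etsevo_bins()
  dur_rec <- nrow(recording$data) / recording$fs
  out <- list()
  for (b in seq_len(nrow(bins))) {
    in_bin <- sevo$concentration >= bins$lo[b] - 1e-9 &
      sevo$concentration < bins$hi[b] - 1e-9
    ep <- NULL
    for (dur in c(30, 20, 15)) {
      # candidate starts: trace seconds t such that samples t..t+dur-1 are
      # all inside the bin and the EEG window fits the recording
      ok <- in_bin & sevo$time + dur <= min(max(sevo$time) + 1, dur_rec)
      cand <- sevo$time[which(ok)]
      cand <- cand[vapply(cand, function(t) {
        idx <- sevo$time >= t & sevo$time < t + dur
        sum(idx) >= dur && all(in_bin[idx])
      }, logical(1))]
      for (t in cand) {
        e <- new_epoch(recording, t, dur, "emergence", etsevo_bin = b)
        if (!attr(artifact_mask(e, artifact_threshold_uv), "rejected")) {
          ep <- e
          break
        }
      }
      if (!is.null(ep)) break
    }
    if (!is.null(ep)) out <- c(out, list(ep))
  }
  out
}
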