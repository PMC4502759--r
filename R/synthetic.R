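#' Oscillator specification
#'
#' One narrowband stochastic oscillator: band-limited randomized-phase noise
#' with a fixed spatial profile across the montage. Oscillators are realized
#' in the frequency domain (random complex coefficients confined to
#' the band center +/- bandwidth/2, inverse FFT, rescaled to the
#' target rms), which gives nonstationary narrowband activity with exactly
#' the configured band support and total power.
#'
#' @param band Band label; one of `"slow"`, `"delta"`, `"theta"`, `"alpha"`,
#'   `"beta"`. The center frequency must lie inside the named band (see
#'   [band_scheme()]).
#' @param center_freq Center frequency, Hz.
#' @param bandwidth Full bandwidth, Hz.
#' @param rms_uv Root-mean-square amplitude of the latent source, microvolts.
#' @param profile Named numeric vector of per-electrode gains in \[0, 1\];
#'   names must be montage labels.
#' @param conc_modulated If TRUE the oscillator's amplitude during emergence
#'   is scaled by min(concentration, 1.2)/1.2, emulating the
#'   concentration-dependent decay of theta/alpha activity.
#' @return A one-row tibble (list-column `profile`).
#' @export
oscillator_spec <- function(band, center_freq, bandwidth, rms_uv, profile,
                            conc_modulated = FALSE) {
  sch <- band_scheme()
  if (!band %in% sch$band) stop("unknown band label: ", band)
  b <- sch[sch$band == band, ]
  if (center_freq < b$lo || center_freq > b$hi) {
    stop("center_freq ", center_freq, " outside the ", band, " band [",
         b$lo, ", ", b$hi, "] Hz")
  }
  stopifnot(rms_uv >= 0, bandwidth > 0)
  if (is.null(names(profile)) || any(profile < 0) || any(profile > 1)) {
    stop("profile must be a named vector of gains in [0, 1]")
  }
  tibble::tibble(band = band, center_freq = center_freq,
                 bandwidth = bandwidth, rms_uv = rms_uv,
                 profile = list(profile), conc_modulated = conc_modulated)
}

#' Default state timeline
#'
#' Contiguous awake, induction, MOSSA (Maintenance Of a Surgical State of
#' Anesthesia) and emergence segments. The MOSSA segment must be at least
#' 600 s so a 10-min constant-concentration window containing a 5-min
#' analysis epoch exists.
#'
#' @param awake,induction,mossa,emergence Segment durations in seconds.
#' @return Tibble with columns `state`, `t_start`, `t_end` (seconds).
#' @export
default_timeline <- function(awake = 40, induction = 60, mossa = 660,
                             emergence = 600) {
  if (mossa < 600) stop("MOSSA segment must be at least 600 s")
  d <- c(awake = awake, induction = induction, mossa = mossa,
         emergence = emergence)
  if (any(d < 0)) stop("segment durations must be non-negative")
  e <- cumsum(d)
  tibble::tibble(state = c("awake", "induction", "MOSSA", "emergence"),
                 t_start = c(0, e[-4]), t_end = unname(e))
}

# broad spatial profile: temporal/lateral dominant, lower on the midline and
# vertex (the surface Laplacian is a spatial high-pass, so the profile needs
# genuine gradients for the oscillation to survive re-referencing)
profile_broad <- function(montage) {
  labs <- montage$positions$label
  incl <- acos(pmin(pmax(montage$positions$z, -1), 1))
  az <- atan2(montage$positions$x, montage$positions$y)
  g <- 0.3 + 0.6 * sin(incl) * (0.4 + 0.6 * abs(sin(az)))
  g <- stats::setNames(pmin(pmax(g, 0), 1), labs)
  g[labs %in% montage$excluded] <- 0.1
  g
}

# lateral frontal profile peaked at F7/F8 (gaussian in great-circle distance)
profile_frontal_lateral <- function(montage, sigma = 0.8) {
  labs <- montage$positions$label
  D <- montage_distances(montage, labs)
  d <- pmin(D[, "F7"], D[, "F8"])
  g <- 0.9 * exp(-d^2 / (2 * sigma^2))
  g[labs %in% montage$excluded] <- 0.05
  stats::setNames(pmin(pmax(g, 0), 1), labs)
}

#' Age-dependent oscillator templates
#'
#' Default oscillators per state. Both cohorts carry slow (0.1-1 Hz) and
#' delta (1-4 Hz) oscillators in every state; only the 4-6 month cohort
#' carries theta (4-8 Hz) and alpha (8-12 Hz) oscillators during induction,
#' MOSSA and emergence (with small awake levels), and the emergence
#' theta/alpha amplitudes decay with end-tidal concentration below 1.2%.
#' Absolute microvolt scales are configuration, not claims about real
#' infant EEG.
#'
#' @param age_group `"0-3mo"` or `"4-6mo"`.
#' @param montage An `eeg_montage`.
#' @return Named list state -> oscillator tibble.
#' @export
default_oscillators <- function(age_group = c("0-3mo", "4-6mo"),
                                montage = default_montage()) {
  age_group <- match.arg(age_group)
  broad <- profile_broad(montage)
  frontal <- profile_frontal_lateral(montage)
  slow  <- oscillator_spec("slow", 0.55, 0.9, 180, broad)
  delta <- oscillator_spec("delta", 2.5, 3, 80, broad)
  base <- dplyr::bind_rows(slow, delta)
  if (age_group == "0-3mo") {
    list(awake = base, induction = base, MOSSA = base, emergence = base)
  } else {
    theta <- oscillator_spec("theta", 6, 4, 30, frontal, conc_modulated = TRUE)
    alpha <- oscillator_spec("alpha", 10, 4, 25, frontal, conc_modulated = TRUE)
    awake_extra <- dplyr::bind_rows(
      oscillator_spec("theta", 6, 4, 8, frontal),
      oscillator_spec("alpha", 10, 4, 6, frontal))
    deep <- dplyr::bind_rows(base, theta, alpha)
    list(awake = dplyr::bind_rows(base, awake_extra),
         induction = deep, MOSSA = deep, emergence = deep)
  }
}

#' Synthetic subject specification
#'
#' @param subject_id Subject identifier string.
#' @param age_group `"0-3mo"` or `"4-6mo"`.
#' @param seed Integer seed; identical specs with identical seeds generate
#'   bit-identical recordings, traces and annotations.
#' @param timeline State timeline tibble (see [default_timeline()]).
#' @param oscillators Named list state -> oscillator tibble (default:
#'   [default_oscillators()] for the age group).
#' @param noise_rms Per-channel independent broadband noise rms, microvolts.
#' @param power_offset_db Cohort-level broadband offset in dB applied to all
#'   oscillator and noise amplitudes (the 0-3 month cohort default is -6 dB,
#'   emulating the overall lower power of the younger infants).
#' @param plateau_pct MOSSA end-tidal sevoflurane plateau, percent.
#' @param fs Native sampling rate, Hz (1024 by default; 256 mirrors the
#'   one lower-rate recording the cohort allows).
#' @param montage An `eeg_montage`.
#' @return A `subject_spec` list.
#' @export
subject_spec <- function(subject_id, age_group = c("0-3mo", "4-6mo"),
                         seed = 1L,
                         timeline = default_timeline(),
                         oscillators = NULL,
                         noise_rms = 2,
                         power_offset_db = if (age_group[1] == "0-3mo") -6 else 0,
                         plateau_pct = if (age_group[1] == "0-3mo") 2.0 else 2.6,
                         fs = 1024,
                         montage = default_montage()) {
  age_group <- match.arg(age_group)
  stopifnot(noise_rms >= 0, plateau_pct >= 0, plateau_pct <= 8)
  check_timeline(timeline)
  if (is.null(oscillators)) {
    oscillators <- default_oscillators(age_group, montage)
  }
  labs <- montage$positions$label
  for (st in names(oscillators)) {
    for (pr in oscillators[[st]]$profile) {
      bad <- setdiff(names(pr), labs)
      if (length(bad) > 0) {
        stop("unknown electrode label(s) in spatial profile: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  structure(list(subject_id = subject_id, age_group = age_group,
                 seed = as.integer(seed) %% 2147483647L,
                 timeline = timeline,
                 oscillators = oscillators, noise_rms = noise_rms,
                 power_offset_db = power_offset_db,
                 plateau_pct = plateau_pct, fs = fs, montage = montage),
            class = "subject_spec")
}

check_timeline <- function(tl) {
  stopifnot(all(c("state", "t_start", "t_end") %in% names(tl)))
  if (nrow(tl) == 0) stop("empty timeline")
  if (any(tl$t_end < tl$t_start)) stop("segment with negative duration")
  if (nrow(tl) > 1 &&
      max(abs(tl$t_start[-1] - tl$t_end[-nrow(tl)])) > 1e-9) {
    stop("timeline segments must be contiguous and non-overlapping")
  }
  invisible(tl)
}

timeline_segment <- function(tl, state) {
  s <- tl[tl$state == state, ]
  if (nrow(s) == 0) return(NULL)
  s[1, ]
}

#' Synthetic end-tidal sevoflurane trace
#'
#' Generates the 1-Hz end-tidal sevoflurane concentration trace implied by a
#' subject's state timeline: 0% while awake, a smooth monotone rise during
#' induction, a plateau held within +/-0.1% of the target during MOSSA, and
#' a smooth monotone decay to exactly 0% across emergence.
#'
#' @param spec A [subject_spec()].
#' @return A `sevo_trace` tibble with columns `time` (s, one sample per
#'   second starting at 0) and `concentration` (%).
#' @export
generate_sevo_profile <- function(spec) {
  tl <- spec$timeline
  mossa <- timeline_segment(tl, "MOSSA")
  if (!is.null(mossa) && mossa$t_end - mossa$t_start <= 0) {
    stop("zero-length MOSSA segment")
  }
  t_total <- max(tl$t_end)
  times <- seq(0, floor(t_total) - 1)
  conc <- numeric(length(times))
  plateau <- spec$plateau_pct
  withr::with_seed(spec$seed + 1, {
    jitter <- stats::runif(length(times), -0.02, 0.02)
  })
  for (k in seq_len(nrow(tl))) {
    seg <- tl[k, ]
    in_seg <- times >= seg$t_start & times < seg$t_end
    u <- (times[in_seg] - seg$t_start) / max(seg$t_end - seg$t_start, 1)
    conc[in_seg] <- switch(
      seg$state,
      awake = 0,
      induction = plateau * u^0.5,          # fast monotone rise
      MOSSA = plateau + 0.05 * sin(2 * pi * u * 4) + jitter[in_seg],
      emergence = plateau * (1 - u)^2,
      0)
  }
  # exact closure: last emergence sample reaches 0 by construction of u<1;
  # force the final second to 0 to guarantee closure on coarse grids
  emer <- timeline_segment(tl, "emergence")
  if (!is.null(emer)) {
    conc[times >= emer$t_end - 1 & times < emer$t_end] <- 0
    idx <- which(times >= emer$t_start & times < emer$t_end)
    conc[idx] <- rev(cummax(rev(conc[idx])))  # enforce monotone decay
  }
  conc <- pmin(pmax(conc, 0), 8)
  out <- tibble::tibble(time = times, concentration = conc)
  class(out) <- c("sevo_trace", class(out))
  attr(out, "subject_id") <- spec$subject_id
  out
}

# band-limited unit-rms noise via frequency-domain synthesis
bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:(floor(n / 2) + ifelse(n %% 2 == 0, 0, 1))  # positive freqs
  in_band <- which(freqs[half] >= f_lo & freqs[half] <= f_hi)
  if (length(in_band) == 0) {
    stop("band [", f_lo, ", ", f_hi, "] Hz contains no DFT bins")
  }
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  k <- half[in_band]
  spec[k] <- complex(real = stats::rnorm(length(k)),
                     imaginary = stats::rnorm(length(k)))
  spec[n - k + 2] <- Conj(spec[k])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

#' Generate one synthetic subject's EEG recording
#'
#' Each timeline segment is a sum of narrowband oscillators (one latent
#' randomized-phase band-limited source per oscillator, multiplied by its
#' per-electrode spatial profile) plus independent per-channel Gaussian
#' noise. During emergence, concentration-modulated oscillators are scaled
#' sample-wise by min(concentration, 1.2)/1.2. The cohort-level power
#' offset scales every amplitude by 10^(power_offset_db/20). Identical
#' specs and seeds give bit-identical output.
#'
#' @param spec A [subject_spec()].
#' @param montage Montage to generate on (default: the spec's montage).
#' @param sevo Optional precomputed [generate_sevo_profile()] trace (used
#'   for concentration modulation; regenerated if NULL).
#' @return An `eeg_recording`: list with `data` (samples x channels matrix,
#'   microvolts, colnames = electrode labels), `fs`, `channels`,
#'   `subject_id`, `age_group`, `timeline`.
#' @export
generate_subject_eeg <- function(spec, montage = spec$montage, sevo = NULL) {
  labs <- montage$positions$label
  fs <- spec$fs
  tl <- spec$timeline
  if (is.null(sevo)) sevo <- generate_sevo_profile(spec)
  n_total <- round(max(tl$t_end) * fs)
  amp_scale <- 10^(spec$power_offset_db / 20)
  data <- NULL
  withr::with_seed(spec$seed, {
    data <- matrix(stats::rnorm(n_total * length(labs),
                                sd = max(spec$noise_rms * amp_scale, 0)),
                   nrow = n_total, ncol = length(labs))
    for (k in seq_len(nrow(tl))) {
      seg <- tl[k, ]
      i0 <- round(seg$t_start * fs) + 1
      i1 <- round(seg$t_end * fs)
      n <- i1 - i0 + 1
      if (n <= 0) next
      osc <- spec$oscillators[[seg$state]]
      if (is.null(osc) || nrow(osc) == 0) next
      seg_t <- (seq_len(n) - 1) / fs + seg$t_start
      S <- matrix(0, n, nrow(osc))
      G <- matrix(0, nrow(osc), length(labs))
      for (j in seq_len(nrow(osc))) {
        src <- bandlimited_noise(n, fs,
                                 osc$center_freq[j] - osc$bandwidth[j] / 2,
                                 osc$center_freq[j] + osc$bandwidth[j] / 2)
        src <- src * osc$rms_uv[j] * amp_scale
        if (isTRUE(osc$conc_modulated[j]) && seg$state == "emergence") {
          ci <- findInterval(seg_t, sevo$time)
          ci[ci < 1] <- 1
          gain <- pmin(sevo$concentration[ci], 1.2) / 1.2
          src <- src * gain
        }
        S[, j] <- src
        g <- osc$profile[[j]][labs]
        g[is.na(g)] <- 0
        G[j, ] <- g
      }
      data[i0:i1, ] <- data[i0:i1, ] + S %*% G
    }
  })
  colnames(data) <- labs
  structure(list(data = data, fs = fs, channels = labs,
                 subject_id = spec$subject_id, age_group = spec$age_group,
                 timeline = tl, t_start = 0),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id %||% "?", ": ",
      ncol(x$data), " channels x ", nrow(x$data), " samples @ ",
      x$fs, " Hz\n", sep = "")
  invisible(x)
}

# triangular draw on [lo, hi] with mode at the midpoint
rtri_mid <- function(n, lo, hi) {
  u <- stats::runif(n)
  m <- 0.5
  ifelse(u < m, lo + (hi - lo) * sqrt(u * m),
         hi - (hi - lo) * sqrt((1 - u) * (1 - m)))
}

#' Synthetic first-movement annotation
#'
#' Draws the concentration at which gross body movement first occurs from a
#' triangular distribution on \[0.2, 1.0\]% (0-3 months) or \[0.3, 0.6\]%
#' (4-6 months) and locates the first time during emergence at which the
#' decaying trace falls to that concentration. By construction no movement
#' ever occurs at 1.2% or greater.
#'
#' @param spec A [subject_spec()].
#' @param sevo The subject's [generate_sevo_profile()] trace.
#' @return A one-row tibble: `subject_id`, `t_first_movement` (s),
#'   `concentration_at_movement` (%), `age_group`.
#' @export
generate_movement_annotation <- function(spec, sevo) {
  emer <- timeline_segment(spec$timeline, "emergence")
  if (is.null(emer)) stop("timeline has no emergence segment")
  rng <- if (spec$age_group == "0-3mo") c(0.2, 1.0) else c(0.3, 0.6)
  withr::with_seed(spec$seed + 2, {
    c_star <- rtri_mid(1, rng[1], rng[2])
  })
  in_emer <- sevo$time >= emer$t_start & sevo$time < emer$t_end
  tt <- sevo$time[in_emer]; cc <- sevo$concentration[in_emer]
  idx <- which(cc <= c_star)[1]
  t_mv <- tt[idx]
  tibble::tibble(subject_id = spec$subject_id,
                 t_first_movement = t_mv,
                 concentration_at_movement = cc[idx],
                 age_group = spec$age_group)
}

#' Cohort specification
#'
#' @param n_young,n_old Number of 0-3 month and 4-6 month subjects (defaults
#'   11 and 19, the cohort sizes the pipeline emulates).
#' @param master_seed Master seed; per-subject seeds are derived
#'   deterministically from it.
#' @param fs Native sampling rate for all subjects.
#' @param fs_exception_subject Index (1..n_young+n_old) of one subject
#'   recorded at 256 Hz instead, or NA for none. Default: the last subject.
#' @param montage An `eeg_montage`.
#' @param ... Additional arguments forwarded to [subject_spec()] (e.g.
#'   `noise_rms`, `timeline`).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_young = 11, n_old = 19, master_seed = 1,
                        fs = 1024,
                        fs_exception_subject = n_young + n_old,
                        montage = default_montage(), ...) {
  if (n_young < 0 || n_old < 0 || n_young + n_old <= 0) {
    stop("group sizes must be non-negative and total at least 1")
  }
  structure(list(n_young = n_young, n_old = n_old,
                 master_seed = as.integer(master_seed),
                 fs = fs, fs_exception_subject = fs_exception_subject,
                 montage = montage, extra = list(...)),
            class = "cohort_spec")
}

#' Generate a full synthetic cohort
#'
#' Generates `n_young + n_old` subjects (default 11 aged 0-3 months and 19
#' aged 4-6 months, 30 in all), each with an EEG recording, a 1-Hz end-tidal
#' sevoflurane trace, and a first-movement annotation. Per-subject seeds are
#' derived from the master seed, so the whole cohort is reproducible
#' bit-exactly.
#'
#' @param cs A [cohort_spec()].
#' @return An `eeg_cohort`: list with `subjects` (list of lists with
#'   elements `recording`, `sevo`, `movement`, `spec`) and `spec`.
#' @export
generate_cohort <- function(cs = cohort_spec()) {
  n <- cs$n_young + cs$n_old
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- generate_cohort_subject(cs, i)
  }
  structure(list(subjects = subjects, spec = cs), class = "eeg_cohort")
}

#' Specification of the i-th cohort subject
#'
#' Deterministic given the cohort spec: per-subject seeds derive from the
#' master seed, the first `n_young` subjects are 0-3 months old, and the
#' `fs_exception_subject` (if any) is generated at 256 Hz.
#'
#' @param cs A [cohort_spec()].
#' @param i Subject index in 1..(n_young + n_old).
#' @return A [subject_spec()].
#' @export
cohort_subject_spec <- function(cs, i) {
  stopifnot(i >= 1, i <= cs$n_young + cs$n_old)
  grp <- if (i <= cs$n_young) "0-3mo" else "4-6mo"
  fs_i <- if (!is.na(cs$fs_exception_subject) &&
              i == cs$fs_exception_subject) 256 else cs$fs
  args <- c(list(subject_id = sprintf("S%02d", i), age_group = grp,
                 seed = derive_seed(cs$master_seed, i), fs = fs_i,
                 montage = cs$montage), cs$extra)
  do.call(subject_spec, args)
}

# one fully generated subject (recording + trace + annotation); the raw
# recording of a default subject is ~370 MB, so large cohorts should be
# generated and processed one subject at a time (as run_pipeline does)
generate_cohort_subject <- function(cs, i) {
  sp <- cohort_subject_spec(cs, i)
  sevo <- generate_sevo_profile(sp)
  rec <- generate_subject_eeg(sp, sevo = sevo)
  mov <- generate_movement_annotation(sp, sevo)
  list(recording = rec, sevo = sevo, movement = mov, spec = sp)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$spec$age_group, character(1))
  cat("<eeg_cohort> ", length(x$subjects), " subjects (",
      sum(groups == "0-3mo"), " aged 0-3mo, ",
      sum(groups == "4-6mo"), " aged 4-6mo)\n", sep = "")
  invisible(x)
}

#' Designed alpha-band contrast between cohorts
#'
#' Expected MOSSA alpha-band (8-12 Hz) power contrast in dB between the two
#' cohort templates at a given electrode, computed analytically from the
#' generator parameters: the older cohort's alpha-band density is its alpha
#' oscillator's flat in-band density (rms^2/bandwidth times the electrode
#' gain squared) plus the broadband noise floor; the younger cohort has
#' noise floor only (scaled by its power offset). Used by parameter-recovery
#' tests to compare measured against designed contrast.
#'
#' @param electrode Electrode label.
#' @param montage An `eeg_montage`.
#' @param noise_rms,power_offset_young_db,fs Generator settings.
#' @return Designed contrast in dB (old minus young alpha-band power).
#' @export
designed_alpha_contrast_db <- function(electrode = "F7",
                                       montage = default_montage(),
                                       noise_rms = 2,
                                       power_offset_young_db = -6,
                                       fs = 1024) {
  old <- default_oscillators("4-6mo", montage)$MOSSA
  a <- old[old$band == "alpha", ]
  gain <- a$profile[[1]][electrode]
  noise_psd <- noise_rms^2 / (fs / 2)              # flat two-sided->one-sided
  alpha_psd <- (a$rms_uv * gain)^2 / a$bandwidth   # flat in-band density
  young_psd <- noise_psd * 10^(power_offset_young_db / 10)
  to_db(alpha_psd + noise_psd) - to_db(young_psd)
}
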