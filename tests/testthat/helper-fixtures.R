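# Small fixtures shared across tests. Subjects are generated at 256 Hz with
# the shortest timeline the epoch rules allow, so generation stays cheap.

quick_timeline <- function() default_timeline(awake = 20, induction = 30,
                                              mossa = 620, emergence = 300)

quick_subject <- function(id = "T01", age_group = "4-6mo", seed = 1,
                          ...) {
  subject_spec(id, age_group, seed = seed, timeline = quick_timeline(),
               fs = 256, montage = test_montage(), ...)
}

# montage is deterministic; build once per test run
test_montage <- local({
  mon <- NULL
  function() {
    if (is.null(mon)) mon <<- default_montage()
    mon
  }
})

# recording + trace for a quick subject, preprocessed to the analysis state
quick_preprocessed <- function(id = "T01", age_group = "4-6mo", seed = 1,
                               ...) {
  sp <- quick_subject(id, age_group, seed, ...)
  sv <- generate_sevo_profile(sp)
  rec <- generate_subject_eeg(sp, sevo = sv)
  w <- build_laplacian_weights(test_montage())
  list(spec = sp, sevo = sv,
       rec = antialias_downsample(apply_laplacian(rec, w)),
       movement = generate_movement_annotation(sp, sv))
}

# bare multichannel epoch from a matrix
matrix_epoch <- function(X, fs = 256, t_start = 0, state = "MOSSA",
                         subject_id = "X", bin = NA_integer_) {
  structure(list(data = X, fs = fs, t_start = t_start,
                 duration = nrow(X) / fs, state = state,
                 etsevo_bin = bin, subject_id = subject_id,
                 age_group = NA_character_),
            class = "eeg_epoch")
}

# fabricate a single-subject spectral_estimate with given linear power rows
fake_estimate <- function(power_db, freqs, times = seq_len(nrow(power_db)),
                          params = multitaper_params(), n_windows = NULL) {
  structure(list(freqs = freqs, times = times, power = power_db,
                 params = params, n_subjects = 1L,
                 n_windows = if (is.null(n_windows)) length(times)
                             else n_windows),
            class = "spectral_estimate")
}

# subject_spectrum with explicit power and dof
fake_spectrum <- function(freqs, power, m = 100) {
  s <- tibble::tibble(freq = freqs, power = power)
  attr(s, "m") <- m
  class(s) <- c("subject_spectrum", class(s))
  s
}
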