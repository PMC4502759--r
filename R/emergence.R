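#' Fraction of subjects moving per concentration bin
#'
#' A subject counts as moving in bin b when its first-movement end-tidal
#' concentration lies inside b's range; the denominator is the number of
#' subjects contributing any EEG epoch to that bin (all annotated subjects
#' when no epoch table is given). Annotations outside \[0, 3)% are assigned
#' to the nearest bin with a message.
#'
#' @param annotations Tibble with one row per subject (`subject_id`,
#'   `concentration_at_movement`).
#' @param epoch_index Optional tibble (`subject_id`, `bin`) saying which
#'   subjects contribute EEG data to which bin.
#' @return Tibble with `bin`, `lo`, `hi`, `n_subjects`, `n_movers`,
#'   `movement_fraction`.
#' @export
movement_fraction_by_bin <- function(annotations, epoch_index = NULL) {
  stopifnot(!anyDuplicated(annotations$subject_id))
  bins <- etsevo_bins()
  conc <- annotations$concentration_at_movement
  idx <- findInterval(conc, c(bins$lo, 3.0), rightmost.closed = FALSE)
  oob <- idx < 1 | idx > nrow(bins)
  if (any(oob)) {
    message(sum(oob), " annotation(s) outside [0, 3)% assigned to the ",
            "nearest bin")
    idx[idx < 1] <- 1
    idx[idx > nrow(bins)] <- nrow(bins)
  }
  movers <- tibble::tibble(subject_id = annotations$subject_id, bin = idx)
  purrr::map_dfr(seq_len(nrow(bins)), function(b) {
    if (is.null(epoch_index)) {
      contributors <- annotations$subject_id
    } else {
      contributors <- unique(epoch_index$subject_id[epoch_index$bin == b])
    }
    n <- length(contributors)
    nm <- sum(movers$bin == b & movers$subject_id %in% contributors)
    tibble::tibble(bin = b, lo = bins$lo[b], hi = bins$hi[b],
                   n_subjects = n, n_movers = nm,
                   movement_fraction = if (n > 0) nm / n else NA_real_)
  })
}

#' Band power per concentration bin
#'
#' For each end-tidal concentration bin, computes each subject's band-mean
#' power (dB, time-mean multitaper spectrum of its binned emergence epoch)
#' and the group median per bin. Missing bins stay absent.
#'
#' @param emergence_epochs List of binned `eeg_epoch`s (from
#'   [bin_emergence_epochs()]) across subjects; each must carry
#'   `etsevo_bin` and `subject_id`.
#' @param scheme A [band_scheme()].
#' @param params A [multitaper_params()].
#' @param channel Channel analyzed (default F7).
#' @return List with `per_subject` (tibble: `subject_id`, `bin`, one column
#'   per band, dB) and `group_median` (tibble: `bin`, `lo`, `hi`,
#'   `n_subjects`, one column per band, dB).
#' @export
band_power_by_bin <- function(emergence_epochs, scheme = band_scheme(),
                              params = multitaper_params(),
                              channel = "F7") {
  stopifnot(length(emergence_epochs) >= 1)
  per_subject <- purrr::map_dfr(emergence_epochs, function(ep) {
    if (is.na(ep$etsevo_bin)) stop("epoch lacks an etSEVO bin")
    se <- multitaper_spectrogram(ep, params, channel = channel, fmax = 30)
    spec_db <- subject_mean_spectrum_db(se)
    vals <- purrr::map_dbl(seq_len(nrow(scheme)), function(b) {
      bins <- band_bins(se$freqs, scheme$lo[b], scheme$hi[b], scheme$band[b])
      mean(spec_db[bins])
    })
    dplyr::bind_cols(
      tibble::tibble(subject_id = ep$subject_id %||% NA_character_,
                     bin = ep$etsevo_bin),
      tibble::as_tibble(stats::setNames(as.list(vals), scheme$band)))
  })
  bins <- etsevo_bins()
  group_median <- per_subject |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     dplyr::across(dplyr::all_of(scheme$band),
                                   stats::median),
                     .groups = "drop") |>
    dplyr::left_join(bins, by = "bin") |>
    dplyr::relocate("bin", "lo", "hi", "n_subjects")
  list(per_subject = per_subject, group_median = group_median)
}
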