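pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Plain EDF (16-bit integer samples, 1-s data records). Each channel's
#' physical range is its observed data range, so round-trip error is at
#' most one quantization step of that range. Trailing samples beyond the
#' last whole second are dropped.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  X <- recording$data
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- round(fs)
  nch <- ncol(X)
  n_rec <- floor(nrow(X) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  X <- X[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- matrixStats::colMins(X)
  pmax_ <- matrixStats::colMaxs(X)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(recording$subject_id %||% "X", 80),
    pad_field("Startdate 01-JAN-2000 synthetic", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (1 + nch), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(nch, 4))
  labs <- recording$channels %||% colnames(X) %||%
    paste0("CH", seq_len(nch))
  sig <- paste0(
    paste0(vapply(labs, pad_field, "", width = 16), collapse = ""),
    paste0(rep(pad_field("AgAgCl electrode", 80), nch), collapse = ""),
    paste0(rep(pad_field("uV", 8), nch), collapse = ""),
    paste0(vapply(sprintf("%.6g", pmin_), pad_field, "", width = 8),
           collapse = ""),
    paste0(vapply(sprintf("%.6g", pmax_), pad_field, "", width = 8),
           collapse = ""),
    paste0(rep(pad_field(dmin, 8), nch), collapse = ""),
    paste0(rep(pad_field(dmax, 8), nch), collapse = ""),
    paste0(rep(pad_field("", 80), nch), collapse = ""),
    paste0(rep(pad_field(fs, 8), nch), collapse = ""),
    paste0(rep(pad_field("", 32), nch), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  # re-read the printed physical ranges so scaling matches what a reader sees
  pmin_r <- as.numeric(sprintf("%.6g", pmin_))
  pmax_r <- as.numeric(sprintf("%.6g", pmax_))
  gain <- (dmax - dmin) / (pmax_r - pmin_r)
  D <- round(sweep(sweep(X, 2, pmin_r), 2, gain, `*`)) + dmin
  D[D < dmin] <- dmin; D[D > dmax] <- dmax
  A <- aperm(array(as.integer(D), dim = c(fs, n_rec, nch)), c(1, 3, 2))
  writeBin(as.integer(A), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a plain EDF file written by [write_edf()] (or any EDF whose
#' signals share one sampling rate), returning samples in physical units.
#'
#' @param path EDF file path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 256) stop("not an EDF file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80 + 80 + 8 + 8)
  subj <- NULL
  seek(con, 8)
  subj <- rd(80)
  seek(con, 8 + 80 + 80 + 8 + 8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1 || is.na(n_rec)) stop("corrupt EDF header")
  rdv <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labs <- rdv(16)
  rdv(80)  # transducer
  rdv(8)   # physical dimension
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)  # prefiltering
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) {
    stop("EDF signals with mixed sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  expected <- hdr_bytes + 2 * as.numeric(n_rec) * sum(spr)
  if (sz < expected) {
    stop("truncated EDF file: ", sz, " bytes, expected ", expected)
  }
  seek(con, hdr_bytes)
  raw_ <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                  signed = TRUE, endian = "little")
  A <- array(raw_, dim = c(spr[1], nch, n_rec))
  X <- matrix(aperm(A, c(1, 3, 2)), ncol = nch)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  X <- sweep(sweep(X, 2, dmin), 2, gain, `*`)
  X <- sweep(X, 2, pmin_, `+`)
  colnames(X) <- labs
  structure(list(data = X, fs = fs, channels = labs,
                 subject_id = subj, age_group = NA_character_,
                 timeline = NULL, t_start = 0),
            class = "eeg_recording")
}

#' Write / read an epoch as flat binary with a JSON sidecar
#'
#' Doubles in native little-endian order (column-major samples x channels)
#' plus a `.json` sidecar carrying the epoch metadata; lossless round-trip.
#'
#' @param epoch An `eeg_epoch`.
#' @param path Path of the binary file (sidecar adds `.json`).
#' @return `path` invisibly (write) or the epoch (read).
#' @export
write_epoch <- function(epoch, path) {
  meta <- list(subject_id = epoch$subject_id, state = epoch$state,
               fs = epoch$fs, t_start = epoch$t_start,
               duration = epoch$duration, etsevo_bin = epoch$etsevo_bin,
               age_group = epoch$age_group,
               channels = colnames(epoch$data),
               n_samples = nrow(epoch$data))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(epoch$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_epoch
#' @export
read_epoch <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  X <- matrix(readBin(con, numeric(), n = meta$n_samples *
                        length(meta$channels), size = 8,
                      endian = "little"),
              nrow = meta$n_samples)
  colnames(X) <- meta$channels
  structure(list(data = X, fs = meta$fs, t_start = meta$t_start,
                 duration = meta$duration, state = meta$state,
                 etsevo_bin = meta$etsevo_bin %||% NA_integer_,
                 subject_id = meta$subject_id,
                 age_group = meta$age_group),
            class = "eeg_epoch")
}
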