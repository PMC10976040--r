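# Minimal EDF (European Data Format) support: fixed 256-byte ASCII header,
# 256 bytes per signal of signal headers, then data records of 16-bit
# little-endian integers mapped linearly from the digital to the physical
# range. Enough for interchange of plain continuous recordings; EDF+
# annotations/discontinuous files are out of scope.

edf_field <- function(con, nchars) {
  raw <- readChar(con, nchars, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < nchars) abort("Unexpected end of EDF header.")
  trimws(raw)
}

pad_field <- function(x, width) {
  x <- as.character(x)
  x <- ifelse(nchar(x, type = "bytes") > width, substr(x, 1, width), x)
  formatC(x, width = -width, flag = " ")
}

#' Read an EDF recording
#'
#' Parses a plain (non-EDF+) European Data Format file and returns the signal
#' matrix in physical units. All channels must share one sampling rate;
#' mixed-rate files (e.g. files with an annotation channel) are rejected.
#' The physical-dimension field is carried along but not enforced; amplitudes
#' are conventionally microvolts for scalp EEG.
#'
#' @param path path to an EDF file.
#' @return An [eeg_recording()] whose `id` is the file's base name.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(paste0("EDF file not found: ", path))
  if (file.size(path) < 256) abort("Not a valid EDF file: header truncated.")
  con <- file(path, "rb")
  on.exit(close(con))

  version <- edf_field(con, 8)
  if (version != "0") abort("Not a valid EDF file: unsupported version field.")
  edf_field(con, 80)              # patient id
  edf_field(con, 80)              # recording id
  edf_field(con, 8)               # start date
  edf_field(con, 8)               # start time
  header_bytes <- suppressWarnings(as.integer(edf_field(con, 8)))
  edf_field(con, 44)              # reserved
  n_records <- suppressWarnings(as.integer(edf_field(con, 8)))
  record_dur <- suppressWarnings(as.numeric(edf_field(con, 8)))
  ns <- suppressWarnings(as.integer(edf_field(con, 4)))
  if (is.na(ns) || ns < 1L) abort("EDF header declares zero signal channels.")
  if (is.na(n_records) || is.na(record_dur) || record_dur <= 0) {
    abort("Malformed EDF header: bad record count or duration.")
  }
  if (is.na(header_bytes) || header_bytes != 256L * (ns + 1L)) {
    abort("Malformed EDF header: header-size field inconsistent with channel count.")
  }

  labels   <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  for (i in seq_len(ns)) edf_field(con, 80)   # transducer
  dims     <- vapply(seq_len(ns), function(i) edf_field(con, 8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  dig_min  <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  dig_max  <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  for (i in seq_len(ns)) edf_field(con, 80)   # prefiltering
  spr      <- as.integer(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  for (i in seq_len(ns)) edf_field(con, 32)   # reserved

  if (any(is.na(spr)) || any(spr < 1L)) abort("Malformed EDF signal headers.")
  if (length(unique(spr)) != 1L) {
    abort("EDF channels have differing sampling rates; resample externally first.")
  }
  if (any(!is.finite(phys_min)) || any(!is.finite(phys_max)) ||
      any(phys_max <= phys_min) || any(dig_max <= dig_min)) {
    abort("Malformed EDF scaling fields.")
  }
  fs <- spr[1] / record_dur

  n_total <- n_records * sum(spr)
  dat <- readBin(con, "integer", n = n_total, size = 2, signed = TRUE,
                 endian = "little")
  if (length(dat) < n_total) abort("EDF data section truncated.")

  signals <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  idx <- 0L
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      block <- dat[(idx + 1L):(idx + spr[ch])]
      signals[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        phys_min[ch] + (block - dig_min[ch]) * gain[ch]
      idx <- idx + spr[ch]
    }
  }
  inform(sprintf("read_edf: %d channel(s), physical dimension(s): %s",
                 ns, paste(unique(dims), collapse = ", ")))
  eeg_recording(signals, fs = fs, channel_names = labels,
                id = tools::file_path_sans_ext(basename(path)))
}

#' Write a recording to EDF
#'
#' Stores the signal matrix as 16-bit EDF with 1-second data records (so `fs`
#' must be a whole number of samples per second). A trailing partial second
#' is zero-padded; quantization error is bounded by half a digital step of
#' each channel's physical range.
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) abort("write_edf requires an integer sampling rate.")
  fs <- as.integer(round(fs))
  x <- recording$signals
  ns <- nrow(x)
  n_records <- as.integer(ceiling(ncol(x) / fs))
  if (ncol(x) < n_records * fs) {
    x <- cbind(x, matrix(0, ns, n_records * fs - ncol(x)))
  }

  phys_min <- apply(x, 1, min); phys_max <- apply(x, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1; phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr(recording$id, 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8); wr("", 44); wr(n_records, 8); wr("1", 8); wr(ns, 4)
  for (ch in seq_len(ns)) wr(recording$channel_names[ch], 16)
  for (ch in seq_len(ns)) wr("", 80)
  for (ch in seq_len(ns)) wr("uV", 8)
  for (ch in seq_len(ns)) wr(signif(phys_min[ch], 7), 8)
  for (ch in seq_len(ns)) wr(signif(phys_max[ch], 7), 8)
  for (ch in seq_len(ns)) wr(dig_min, 8)
  for (ch in seq_len(ns)) wr(dig_max, 8)
  for (ch in seq_len(ns)) wr("", 80)
  for (ch in seq_len(ns)) wr(fs, 8)
  for (ch in seq_len(ns)) wr("", 32)

  # re-read the physical bounds exactly as a reader will parse them, so the
  # digital mapping inverts without an extra rounding step
  pmin_r <- as.numeric(pad_field(signif(phys_min, 7), 8))
  pmax_r <- as.numeric(pad_field(signif(phys_max, 7), 8))
  gain <- (dig_max - dig_min) / (pmax_r - pmin_r)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      seg <- x[ch, ((r - 1L) * fs + 1L):(r * fs)]
      dig <- round(dig_min + (seg - pmin_r[ch]) * gain[ch])
      dig <- as.integer(pmin(pmax(dig, dig_min), dig_max))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
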