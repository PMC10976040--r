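#' Construct an EEG recording object
#'
#' Bundles a channels-by-samples signal matrix with its sampling rate and
#' channel names. Amplitudes are assumed to be in microvolts; times are
#' seconds from recording start.
#'
#' @param signals numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector, one name per row of `signals`.
#'   Defaults to `"ch1"`, `"ch2"`, ...
#' @param id identifier used to key feature-table rows.
#'
#' @return An object of class `eeg_recording` with fields `signals`, `fs`,
#'   `channel_names`, `duration_s` and `id`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(512), nrow = 2), fs = 256)
#' rec$duration_s
eeg_recording <- function(signals, fs, channel_names = NULL, id = "recording") {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  stopifnot(is.matrix(signals), is.numeric(signals))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive finite scalar (Hz).")
  }
  nch <- nrow(signals)
  if (nch < 1L) abort("Recording must contain at least one channel.")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  if (length(channel_names) != nch) {
    abort("`channel_names` must have one entry per signal row.")
  }
  rownames(signals) <- channel_names
  structure(
    list(
      signals = signals,
      fs = fs,
      channel_names = channel_names,
      duration_s = ncol(signals) / fs,
      id = id
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording '%s'> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    x$id, nrow(x$signals), ncol(x$signals), x$fs, x$duration_s
  ))
  cat("channels:", paste(head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read seizure annotations from CSV
#'
#' The canonical annotation dialect is a 3-column CSV with header
#' `onset_s,offset_s,label`, times in seconds from recording start, and
#' intervals half-open `[onset, offset)`. Overlapping (or touching) seizure
#' intervals are merged on load and the result is sorted by onset.
#'
#' @param path path to the annotation CSV.
#' @param duration_s optional recording duration; when supplied, intervals
#'   outside `[0, duration_s]` raise an error.
#'
#' @return A tibble with columns `onset_s`, `offset_s`, `label`, sorted and
#'   free of overlaps.
#' @export
read_annotations <- function(path, duration_s = NULL) {
  if (!file.exists(path)) abort(paste0("Annotation file not found: ", path))
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("onset_s", "offset_s", "label")
  if (!all(req %in% names(ann))) {
    abort("Annotation CSV must have columns onset_s, offset_s, label.")
  }
  annotation_set(ann$onset_s, ann$offset_s, ann$label, duration_s = duration_s)
}

#' Build a validated annotation set
#'
#' @param onset_s,offset_s interval bounds in seconds (half-open).
#' @param label interval labels; only `"seizure"` is recognised.
#' @param duration_s optional recording duration for range checking.
#' @return A sorted, overlap-merged tibble of seizure intervals.
#' @export
annotation_set <- function(onset_s, offset_s = NULL, label = "seizure",
                           duration_s = NULL) {
  if (is.data.frame(onset_s)) {
    df <- onset_s
    onset_s <- df$onset_s; offset_s <- df$offset_s
    label <- df$label %||% rep("seizure", length(onset_s))
  }
  if (length(onset_s) == 0L) {
    return(tibble(onset_s = double(), offset_s = double(), label = character()))
  }
  label <- rep_len(as.character(label), length(onset_s))
  if (!all(label %in% "seizure")) {
    abort(paste0("Unknown annotation label(s): ",
                 paste(setdiff(unique(label), "seizure"), collapse = ", ")))
  }
  if (any(!is.finite(onset_s)) || any(!is.finite(offset_s))) {
    abort("Annotation times must be finite.")
  }
  if (any(onset_s >= offset_s)) {
    abort("Each annotation must satisfy onset_s < offset_s.")
  }
  if (any(onset_s < 0)) abort("Annotation onsets must be >= 0.")
  if (!is.null(duration_s) && any(offset_s > duration_s + 1e-9)) {
    abort("Annotation interval extends beyond the recording duration.")
  }
  o <- order(onset_s)
  onset_s <- onset_s[o]; offset_s <- offset_s[o]
  # merge overlapping / touching intervals
  m_on <- onset_s[1]; m_off <- offset_s[1]
  out_on <- double(); out_off <- double()
  for (i in seq_along(onset_s)[-1]) {
    if (onset_s[i] <= m_off) {
      m_off <- max(m_off, offset_s[i])
    } else {
      out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
      m_on <- onset_s[i]; m_off <- offset_s[i]
    }
  }
  out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
  tibble(onset_s = out_on, offset_s = out_off,
         label = rep("seizure", length(out_on)))
}

#' Write annotations to the canonical CSV dialect
#'
#' @param annotations tibble with `onset_s`, `offset_s`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[, c("onset_s", "offset_s", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a feature table to CSV
#'
#' Columns are `recording_id, channel, t_start_s, m, f_1..f_{m^2+2m},
#' fit_pct, label`. The round trip through [read_feature_table()] is lossless
#' for values, labels and grouping keys.
#'
#' @param table feature table as produced by [extract_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    abort("Feature table must be a non-empty data frame.")
  }
  m <- unique(table$m)
  if (length(m) != 1L) abort("Feature table mixes model orders.")
  fcols <- grep("^f_\\d+$", names(table), value = TRUE)
  if (length(fcols) != m^2 + 2 * m) {
    abort(sprintf("Expected %d feature columns for order m=%d, found %d.",
                  m^2 + 2 * m, m, length(fcols)))
  }
  readr::write_csv(table, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path path to the CSV.
#' @param m optional declared model order; if it disagrees with the file's
#'   feature-column count an error is raised.
#' @return A tibble feature table.
#' @export
read_feature_table <- function(path, m = NULL) {
  if (!file.exists(path)) abort(paste0("Feature table not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0L) abort("Feature table file contains no rows.")
  fcols <- grep("^f_\\d+$", names(tab), value = TRUE)
  m_file <- unique(tab$m)
  if (length(m_file) != 1L) abort("Feature table mixes model orders.")
  if (length(fcols) != m_file^2 + 2 * m_file) {
    abort("Feature-column count disagrees with the stored model order.")
  }
  if (!is.null(m) && m != m_file) {
    abort(sprintf(
      "Declared order m=%d but file stores m=%d (%d feature columns).",
      m, m_file, length(fcols)))
  }
  tab$label <- as.integer(tab$label)
  tab
}
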