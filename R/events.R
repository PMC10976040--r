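#' Collapse per-epoch predictions into 30-second decision windows
#'
#' Non-overlapping windows are tiled from t = 0; each epoch belongs to the
#' window containing its start time. A window is declared seizure-positive
#' when strictly more than 50% of its epochs are predicted positive
#' (exactly half is negative). A trailing partial window is scored by the
#' same rule over the epochs it contains.
#'
#' @param pred integer 0/1 vector of per-epoch predictions.
#' @param start_times_s epoch start times in seconds (sorted).
#' @param window_s window length in seconds (default 30).
#' @param duration_s optional recording duration; windows are tiled to cover
#'   it even where no epochs fall.
#' @return A tibble with one row per window: `index`, `start_s`, `end_s`,
#'   `n_epochs`, `n_positive`, `positive`.
#' @export
window_decisions <- function(pred, start_times_s, window_s = 30,
                             duration_s = NULL) {
  if (length(pred) == 0L) abort("No epoch predictions supplied.")
  if (length(pred) != length(start_times_s)) {
    abort("Predictions and start times differ in length.")
  }
  if (is.unsorted(start_times_s)) abort("Epoch start times must be sorted.")
  pred <- as.integer(pred)
  total_end <- duration_s %||% (max(start_times_s) + window_s / 2)
  n_win <- max(1L, as.integer(ceiling(total_end / window_s)))
  widx <- pmin(floor(start_times_s / window_s), n_win - 1L)
  counts <- tabulate(widx + 1L, nbins = n_win)
  pos <- vapply(seq_len(n_win) - 1L, function(w) sum(pred[widx == w]),
                integer(1))
  tibble(
    index = seq_len(n_win),
    start_s = (seq_len(n_win) - 1) * window_s,
    end_s = pmin(seq_len(n_win) * window_s, max(total_end, window_s)),
    n_epochs = counts,
    n_positive = pos,
    positive = counts > 0 & pos / pmax(counts, 1L) > 0.5
  )
}

interval_overlaps <- function(a_start, a_end, b_start, b_end) {
  # half-open [start, end) intervals
  outer(a_start, b_end, `<`) & outer(a_end, b_start, `>`)
}

#' Score window decisions against seizure annotations
#'
#' A positive window overlapping any annotated seizure is a true window;
#' a positive window overlapping none is a false window. Maximal runs of
#' consecutive false windows count as a single false detection. A seizure
#' is detected when some true window overlaps it; its latency is the end
#' time of the first such window minus the seizure onset (the decision is
#' emitted when the window closes).
#'
#' @param decisions window tibble from [window_decisions()].
#' @param annotations seizure [annotation_set()] tibble.
#' @param duration_h recording duration in hours (for the false-detection
#'   rate).
#' @param recording_id identifier carried into reports.
#' @return An `event_report`: list with `recording_id`, `duration_h`,
#'   `windows` (decisions plus a `truth` column), `seizures` (per-seizure
#'   `detected` flag and `latency_s`), `n_seizures`, `n_detected`,
#'   `false_detections`, `fd_per_hour`.
#' @export
score_events <- function(decisions, annotations, duration_h,
                         recording_id = "recording") {
  if (!is.numeric(duration_h) || duration_h <= 0) {
    abort("`duration_h` must be positive.")
  }
  ann <- annotation_set(annotations)
  posw <- decisions[decisions$positive, , drop = FALSE]
  if (nrow(ann) > 0L && nrow(posw) > 0L) {
    ov <- interval_overlaps(posw$start_s, posw$end_s, ann$onset_s, ann$offset_s)
    true_win <- rowSums(ov) > 0
  } else {
    ov <- matrix(FALSE, nrow(posw), nrow(ann))
    true_win <- rep(FALSE, nrow(posw))
  }
  false_idx <- posw$index[!true_win]
  n_fd <- count_runs(false_idx)

  if (nrow(ann) > 0L) {
    seiz <- purrr::map_dfr(seq_len(nrow(ann)), function(s) {
      hits <- which(true_win & ov[, s])
      detected <- length(hits) > 0
      tibble(
        onset_s = ann$onset_s[s], offset_s = ann$offset_s[s],
        detected = detected,
        latency_s = if (detected) min(posw$end_s[hits]) - ann$onset_s[s]
                    else NA_real_
      )
    })
  } else {
    seiz <- tibble(onset_s = double(), offset_s = double(),
                   detected = logical(), latency_s = double())
  }

  windows <- decisions
  windows$truth <- "negative"
  windows$truth[match(posw$index[true_win], windows$index)] <- "true"
  windows$truth[match(false_idx, windows$index)] <- "false"

  structure(
    list(
      recording_id = recording_id, duration_h = duration_h,
      windows = windows, seizures = seiz,
      n_seizures = nrow(seiz), n_detected = sum(seiz$detected),
      false_detections = n_fd,
      fd_per_hour = fd_per_hour(n_fd, duration_h)
    ),
    class = "event_report"
  )
}

# number of maximal runs of consecutive integers
count_runs <- function(idx) {
  if (length(idx) == 0L) return(0L)
  idx <- sort(idx)
  sum(diff(idx) > 1L) + 1L
}

#' False detections per hour
#'
#' @param count merged false-detection count.
#' @param duration_h recording duration in hours.
#' @return The rate `count / duration_h` (tables conventionally print it to
#'   one decimal).
#' @export
fd_per_hour <- function(count, duration_h) {
  if (!is.numeric(duration_h) || any(duration_h <= 0)) {
    abort("`duration_h` must be positive.")
  }
  count / duration_h
}

#' @export
print.event_report <- function(x, ...) {
  cat(sprintf(
    "<event_report '%s'> %.1f h | %d/%d seizures detected | %d false detection(s) (%.2f /h)\n",
    x$recording_id, x$duration_h, x$n_detected, x$n_seizures,
    x$false_detections, x$fd_per_hour
  ))
  invisible(x)
}

#' @describeIn score_events per-window tibble with the truth marking.
#' @param x an `event_report`.
#' @param ... unused.
#' @method tidy event_report
#' @export
tidy.event_report <- function(x, ...) x$windows

#' @describeIn score_events one-row summary tibble.
#' @method glance event_report
#' @export
glance.event_report <- function(x, ...) {
  tibble(
    recording_id = x$recording_id, duration_h = x$duration_h,
    n_seizures = x$n_seizures, n_detected = x$n_detected,
    false_detections = x$false_detections, fd_per_hour = x$fd_per_hour,
    mean_latency_s = mean(x$seizures$latency_s[x$seizures$detected])
  )
}

#' Aggregate per-recording event reports
#'
#' Accepts a list of `event_report`s or a per-recording summary data frame
#' with columns `duration_h`, `n_seizures`, `false_detections`,
#' `fd_per_hour`. Produces the conventional summary block: column totals,
#' per-recording means, and population (divide-by-n) standard deviations.
#'
#' @param reports list of event reports, or a summary tibble.
#' @return An `event_summary`: list with `per_recording` (tibble) and
#'   `aggregate` (tibble with rows `total`, `average`, `stdev`).
#' @export
aggregate_reports <- function(reports) {
  per <- if (is.data.frame(reports)) {
    as_tibble(reports)
  } else {
    if (length(reports) == 0L) abort("No reports to aggregate.")
    purrr::map_dfr(reports, glance)
  }
  req <- c("duration_h", "n_seizures", "false_detections", "fd_per_hour")
  if (!all(req %in% names(per))) {
    abort(paste0("Per-recording summary needs columns: ",
                 paste(req, collapse = ", ")))
  }
  if (nrow(per) == 0L) abort("No reports to aggregate.")
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  agg <- tibble(
    stat = c("total", "average", "stdev"),
    duration_h = c(sum(per$duration_h), mean(per$duration_h),
                   sd_pop(per$duration_h)),
    n_seizures = c(sum(per$n_seizures), mean(per$n_seizures),
                   sd_pop(per$n_seizures)),
    false_detections = c(sum(per$false_detections),
                         mean(per$false_detections),
                         sd_pop(per$false_detections)),
    fd_per_hour = c(NA_real_, mean(per$fd_per_hour), sd_pop(per$fd_per_hour))
  )
  structure(list(per_recording = per, aggregate = agg),
            class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("<event_summary> %d recording(s)\n", nrow(x$per_recording)))
  print(x$aggregate)
  invisible(x)
}

#' @describeIn aggregate_reports the total/average/stdev block.
#' @param x an `event_summary`.
#' @param ... unused.
#' @method glance event_summary
#' @export
glance.event_summary <- function(x, ...) x$aggregate

#' @describeIn aggregate_reports the per-recording rows.
#' @method tidy event_summary
#' @export
tidy.event_summary <- function(x, ...) x$per_recording

#' Fuse per-epoch predictions across channels
#'
#' @param pred_matrix channels-by-epochs 0/1 matrix.
#' @param rule `"majority"` (default), `"any"`, or `"all"`.
#' @return Integer 0/1 vector, one entry per epoch.
#' @export
fuse_predictions <- function(pred_matrix, rule = c("majority", "any", "all")) {
  rule <- match.arg(rule)
  if (is.vector(pred_matrix)) pred_matrix <- matrix(pred_matrix, nrow = 1)
  frac <- colMeans(pred_matrix)
  as.integer(switch(rule,
    majority = frac > 0.5,
    any = frac > 0,
    all = frac == 1
  ))
}
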