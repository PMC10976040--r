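#' Flatten a realization into a classifier feature vector
#'
#' Concatenates the state matrices in fixed order: `A` row-major
#' (`a11..a1m, a21..amm`), then `c1..cm`, then `k1..km`, giving
#' `m^2 + 2m` values per epoch.
#'
#' @param model an `ss_realization` (or list with `A`, `C`, `K`, `m`).
#' @return Numeric vector of length `m^2 + 2m`.
#' @export
#' @examples
#' mod <- list(m = 2, A = diag(2), C = matrix(1:2, 1), K = matrix(3:4, 2))
#' to_feature_vector(mod)  # 1 0 0 1 1 2 3 4
to_feature_vector <- function(model) {
  m <- model$m
  if (!all(dim(model$A) == c(m, m)) || length(model$C) != m ||
      length(model$K) != m) {
    abort("Realization matrices do not match the declared order.")
  }
  c(as.vector(t(model$A)), as.vector(model$C), as.vector(model$K))
}

#' Reassemble state matrices from a feature vector
#'
#' Inverse of [to_feature_vector()]; exact round trip.
#'
#' @param v numeric vector of length `m^2 + 2m`.
#' @param m model order.
#' @return List with `A`, `C`, `K`, `m`.
#' @export
unflatten_features <- function(v, m) {
  if (length(v) != m^2 + 2 * m) {
    abort(sprintf("Expected %d values for order %d, got %d.",
                  m^2 + 2 * m, m, length(v)))
  }
  list(
    m = m,
    A = matrix(v[seq_len(m^2)], nrow = m, byrow = TRUE),
    C = matrix(v[m^2 + seq_len(m)], nrow = 1),
    K = matrix(v[m^2 + m + seq_len(m)], ncol = 1)
  )
}

feature_names <- function(m) paste0("f_", seq_len(m^2 + 2 * m))

#' Label epochs from seizure annotations
#'
#' An epoch spanning `[t, t + epoch_len_s)` is labelled seizure (1) when at
#' least half of its span overlaps an annotated seizure interval, else
#' non-seizure (0). With half-overlapping epochs this majority rule resolves
#' onset/offset boundaries symmetrically.
#'
#' @param epoch_set a [make_epochs()] result.
#' @param annotations a seizure [annotation_set()] tibble (may be empty).
#' @return Integer vector of 0/1 labels, one per epoch.
#' @export
label_epochs <- function(epoch_set, annotations) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  starts <- epoch_set$start_times_s
  len <- epoch_set$epoch_len_s
  if (is.null(annotations) || nrow(annotations) == 0L) {
    return(integer(length(starts)))
  }
  overlap <- vapply(starts, function(t0) {
    sum(pmax(0, pmin(t0 + len, annotations$offset_s) -
                pmax(t0, annotations$onset_s)))
  }, numeric(1))
  as.integer(overlap >= len / 2)
}

#' Extract per-epoch state-space features from a recording
#'
#' For each selected channel: band-pass and notch filter the whole channel,
#' cut it into half-overlapping epochs, estimate an order-`m` state-space
#' model per epoch, flatten the state matrices into a feature row, and
#' attach the annotation-derived label. Rows whose realization is flagged
#' degenerate (or contains non-finite values) are dropped and counted.
#'
#' @param recording an [eeg_recording()].
#' @param annotations seizure annotations tibble, or `NULL` for all-zero
#'   labels.
#' @param channels channel names or indices to process (default: all).
#' @param m model order (default 5).
#' @param epoch_len_s epoch length in seconds (default 1).
#' @param config pipeline configuration from [default_config()]; the filter
#'   band, notch and tolerances are read from here.
#' @return A tibble with columns `recording_id`, `channel`, `t_start_s`,
#'   `m`, `f_1..f_{m^2+2m}`, `fit_pct`, `label`.
#' @export
extract_features <- function(recording, annotations = NULL, channels = NULL,
                             m = 5, epoch_len_s = 1,
                             config = default_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(channels)) channels <- recording$channel_names
  if (is.numeric(channels)) channels <- recording$channel_names[channels]
  missing_ch <- setdiff(channels, recording$channel_names)
  if (length(missing_ch)) {
    abort(paste0("Channel(s) not in recording: ",
                 paste(missing_ch, collapse = ", ")))
  }
  if (length(channels) == 0L) abort("No channels selected.")

  rows <- purrr::map(channels, function(ch) {
    x <- recording$signals[match(ch, recording$channel_names), ]
    if (isTRUE(config$apply_filters)) {
      x <- bandpass_filter(x, recording$fs, low = config$band_low_hz,
                           high = config$band_high_hz,
                           order = config$butter_order)
      x <- suppressWarnings(
        notch_filter(x, recording$fs, f0 = config$notch_hz, Q = config$notch_q))
    }
    es <- make_epochs(x, recording$fs, epoch_len_s, channel = ch)
    labels <- label_epochs(es, annotations)
    p <- nrow(es$epochs)
    feats <- matrix(NA_real_, nrow = p, ncol = m^2 + 2 * m)
    fit <- numeric(p)
    degen <- logical(p)
    for (i in seq_len(p)) {
      mod <- withCallingHandlers(
        estimate_model(es$epochs[i, ], m = m, svd_tol = config$svd_tol,
                       instability_tol = config$instability_tol),
        warning = function(w) invokeRestart("muffleWarning")
      )
      degen[i] <- isTRUE(mod$degenerate)
      if (!degen[i]) {
        feats[i, ] <- to_feature_vector(mod)
        fit[i] <- mod$fit_pct
      }
    }
    keep <- !degen & apply(feats, 1, function(r) all(is.finite(r)))
    k <- sum(keep)
    out <- as_tibble(setNames(as.data.frame(feats[keep, , drop = FALSE]),
                              feature_names(m)))
    res <- dplyr::bind_cols(
      tibble(
        recording_id = rep(recording$id, k), channel = rep(ch, k),
        t_start_s = es$start_times_s[keep], m = rep(as.integer(m), k)
      ),
      out,
      tibble(fit_pct = fit[keep], label = labels[keep])
    )
    attr(res, "n_dropped") <- sum(!keep)
    res
  })
  dropped <- sum(vapply(rows, function(r) attr(r, "n_dropped"), numeric(1)))
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0L) abort("All epochs produced degenerate models.")
  if (dropped > 0) {
    inform(sprintf("extract_features: dropped %d degenerate epoch model(s).",
                   dropped))
  }
  tab
}
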