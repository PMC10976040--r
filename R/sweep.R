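#' Sweep model orders, epoch lengths and classifiers
#'
#' Reruns the full feature-extraction + cross-validation pipeline over a
#' grid of model orders, epoch lengths and classifiers on one recording
#' (real or synthetic), mirroring the usual order/epoch-length selection
#' experiments. Deterministic for a fixed seed.
#'
#' @param recording an [eeg_recording()].
#' @param annotations seizure annotations tibble.
#' @param channels channels to pool (default: first channel).
#' @param orders model orders to try (default `3:10`).
#' @param epoch_lens epoch lengths in seconds (default 1).
#' @param classifiers classifier names (default `"decision_tree"`).
#' @param k cross-validation folds.
#' @param seed RNG seed.
#' @param config pipeline configuration.
#' @return A `sweep_report`: tibble with one row per
#'   (order, epoch length, classifier) carrying the mean CV metrics; the
#'   full `cv_report`s are in the `reports` attribute.
#' @export
run_sweep <- function(recording, annotations, channels = 1,
                      orders = 3:10, epoch_lens = 1,
                      classifiers = "decision_tree", k = 10,
                      seed = 20240316, config = default_config()) {
  grid <- tidyr::expand_grid(m = orders, epoch_len_s = epoch_lens)
  reports <- list()
  rows <- purrr::pmap_dfr(grid, function(m, epoch_len_s) {
    tab <- extract_features(recording, annotations, channels = channels,
                            m = m, epoch_len_s = epoch_len_s,
                            config = config)
    purrr::map_dfr(classifiers, function(cl) {
      cv <- cross_validate(tab, classifier = cl, k = k, seed = seed)
      reports[[sprintf("m%d_e%g_%s", m, epoch_len_s, cl)]] <<- cv
      dplyr::bind_cols(
        tibble(m = m, epoch_len_s = epoch_len_s),
        glance(cv)[c("classifier", "sensitivity", "specificity", "accuracy")]
      )
    })
  })
  structure(rows, reports = reports, class = c("sweep_report", class(rows)))
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("<sweep_report>\n")
  NextMethod()
}

#' Plot a sweep as accuracy versus model order
#'
#' @param object a `sweep_report`.
#' @param metric column to plot (default accuracy).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot sweep_report
#' @export
autoplot.sweep_report <- function(object, metric = "accuracy", ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$m, y = .data[[metric]],
    colour = .data$classifier, group = .data$classifier
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "model order", y = metric,
                  title = "Classifier performance across model orders") +
    ggplot2::theme_minimal()
}

#' Detect seizure events in a continuous recording
#'
#' End-to-end detection: extract per-epoch features on the selected
#' channels, predict with a trained classifier, fuse channel votes, apply
#' the 30-s majority decision window, and score against annotations.
#'
#' @param recording an [eeg_recording()].
#' @param model a trained [train_final()] classifier.
#' @param annotations ground-truth seizure annotations used for scoring.
#' @param channels channels to use (default: all the recording has).
#' @param epoch_len_s epoch length in seconds.
#' @param window_s decision window length in seconds.
#' @param fusion channel-vote fusion rule (see [fuse_predictions()]).
#' @param config pipeline configuration.
#' @return An `event_report` from [score_events()].
#' @export
detect_events <- function(recording, model, annotations,
                          channels = NULL, epoch_len_s = 1, window_s = 30,
                          fusion = "majority", config = default_config()) {
  feats <- extract_features(recording, annotations = NULL,
                            channels = channels, m = model$m,
                            epoch_len_s = epoch_len_s, config = config)
  feats$pred <- predict(model, feats)
  fusion <- match.arg(fusion, c("majority", "any", "all"))
  fuse_fn <- switch(fusion,
    majority = function(p) as.integer(mean(p) > 0.5),
    any = function(p) as.integer(any(p == 1)),
    all = function(p) as.integer(all(p == 1))
  )
  # one fused 0/1 per epoch start time across channels
  fused <- feats |>
    dplyr::group_by(.data$t_start_s) |>
    dplyr::summarise(pred = fuse_fn(.data$pred), .groups = "drop") |>
    dplyr::arrange(.data$t_start_s)
  dec <- window_decisions(fused$pred, fused$t_start_s, window_s = window_s,
                          duration_s = recording$duration_s)
  score_events(dec, annotations, duration_h = recording$duration_s / 3600,
               recording_id = recording$id)
}

#' Plot an event report timeline
#'
#' Decision windows coloured by outcome with annotated seizure spans
#' underneath.
#'
#' @param object an `event_report`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot event_report
#' @export
autoplot.event_report <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = w,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = 0, ymax = 1, fill = .data$truth)
    ) +
    ggplot2::geom_rect(
      data = object$seizures,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -0.4, ymax = -0.1),
      fill = "firebrick"
    ) +
    ggplot2::scale_fill_manual(values = c(negative = "grey90",
                                          true = "seagreen",
                                          false = "orange")) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "window",
                  title = sprintf("Detections: %s (%.2f FD/h)",
                                  object$recording_id, object$fd_per_hour)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `cv_report`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds,
                              c("sensitivity", "specificity", "accuracy"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(long$fold)) +
    ggplot2::labs(title = sprintf("%d-fold CV: %s", object$k,
                                  object$classifier),
                  y = "metric value") +
    ggplot2::theme_minimal()
}

#' Plot an epoch against its model's free-run simulation
#'
#' @param epoch numeric epoch vector.
#' @param model an `ss_realization` for that epoch.
#' @param fs sampling rate in Hz (for the time axis).
#' @return A ggplot.
#' @export
plot_model_fit <- function(epoch, model, fs = 1) {
  y_sim <- suppressWarnings(simulate_output(model, epoch))
  df <- tibble(
    t = rep((seq_along(epoch) - 1) / fs, 2),
    value = c(epoch, as.numeric(y_sim)),
    series = rep(c("epoch", "simulation"), each = length(epoch))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = sprintf("Order-%d model, fit %.1f%%", model$m,
                                  suppressWarnings(fit_nrmse(epoch, y_sim)))) +
    ggplot2::theme_minimal()
}
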