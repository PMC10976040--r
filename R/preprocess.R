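#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 0.5--29 Hz, order 2) forward and
#' backward, so the output has no phase distortion and the effective
#' magnitude response is the square of the single-pass response. The band
#' keeps the clinically relevant EEG rhythms while removing slow drift and
#' high-frequency artifact.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz; must exceed `2 * high`.
#' @param low,high band edges in Hz.
#' @param order Butterworth design order of the single pass.
#' @return Filtered vector of the same length.
#' @export
#' @examples
#' y <- bandpass_filter(sin(2 * pi * 10 * (0:999) / 250), fs = 250)
bandpass_filter <- function(x, fs, low = 0.5, high = 29, order = 2) {
  check_signal(x)
  if (fs <= 2 * high) {
    abort("Sampling rate must exceed twice the upper band edge.")
  }
  if (length(x) <= 3 * (2 * order + 1)) {
    abort("Signal too short for the filter's warm-up.")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  zero_phase(bf, x)
}

#' Zero-phase power-line notch filter
#'
#' Second-order IIR notch (constrained biquad) centred on the mains
#' frequency, applied forward-backward. If the sampling rate cannot
#' represent the notch frequency (`fs <= 2 * f0`) the signal is returned
#' unchanged with a warning.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param f0 notch centre frequency in Hz (60 for North American mains).
#' @param Q quality factor; bandwidth is `f0 / Q`.
#' @return Filtered vector of the same length.
#' @export
notch_filter <- function(x, fs, f0 = 60, Q = 30) {
  check_signal(x)
  if (fs <= 2 * f0) {
    warn(sprintf(
      "notch_filter: fs = %g Hz cannot represent a %g Hz notch; skipped.", fs, f0))
    return(x)
  }
  nf <- design_notch(fs, f0, Q)
  zero_phase(nf, x)
}

# Forward-backward filtering. Each pass pads with an odd (point-symmetric)
# reflection about the data edges -- value- and slope-continuous there, so
# start-up transients ring in the padding, not the data -- sized to several
# time constants of the filter's slowest pole. Padding is rebuilt per pass;
# reusing the forward padding would leave constant-offset steps at the
# boundaries for the backward pass of a unit-DC-gain filter (the notch).
zero_phase <- function(flt, x) {
  b <- flt$b; a <- flt$a
  r <- suppressWarnings(max(Mod(polyroot(rev(a)))))
  P <- if (is.finite(r) && r < 1) ceiling(8 / (1 - r)) else 10L * length(a)
  P <- max(P, 3L * (length(a) + length(b)))
  P <- min(P, length(x) - 1L)
  y1 <- padded_pass(flt, x, P)
  rev(padded_pass(flt, rev(y1), P))
}

padded_pass <- function(flt, x, P) {
  n <- length(x)
  pre <- 2 * x[1] - x[(P + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - P)]
  as.numeric(signal::filter(flt, c(pre, x, post)))[(P + 1L):(P + n)]
}

# Standard audio-EQ biquad notch: unit gain at DC and Nyquist, zero at f0.
design_notch <- function(fs, f0, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

check_signal <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) abort("Signal must be a numeric vector.")
  if (any(!is.finite(x))) abort("Signal contains non-finite samples.")
  invisible(x)
}

#' Cut a single-channel signal into half-overlapping epochs
#'
#' Epochs are `n = fs * epoch_len_s` samples long and advance by `n/2`
#' samples, so consecutive epochs share exactly half their samples (for odd
#' `n` the increment is `floor(n/2)`). At 1000 Hz with 1-s epochs this gives
#' `floor(L/500 - 1)` epochs from `L` samples. Trailing samples that do not
#' fill a full epoch are dropped.
#'
#' @param x numeric signal vector (already filtered).
#' @param fs sampling rate in Hz.
#' @param epoch_len_s epoch length in seconds (typically 1, 2, 5 or 10).
#' @param channel optional channel name carried into downstream tables.
#' @return An `epoch_set`: list with `epochs` (p x n matrix), `n`, `fs`,
#'   `epoch_len_s`, `increment` (samples), `start_times_s` and `channel`.
#' @export
#' @examples
#' es <- make_epochs(rnorm(10000), fs = 1000, epoch_len_s = 1)
#' nrow(es$epochs)  # 19
make_epochs <- function(x, fs, epoch_len_s, channel = "ch1") {
  check_signal(x)
  n <- fs * epoch_len_s
  if (abs(n - round(n)) > 1e-9) {
    abort("fs * epoch_len_s must be a whole number of samples.")
  }
  n <- as.integer(round(n))
  L <- length(x)
  if (L < n) abort("Signal shorter than one epoch.")
  inc <- n %/% 2L
  p <- (L - n) %/% inc + 1L
  starts <- (seq_len(p) - 1L) * inc + 1L
  epochs <- matrix(0, nrow = p, ncol = n)
  for (i in seq_len(p)) epochs[i, ] <- x[starts[i]:(starts[i] + n - 1L)]
  structure(
    list(
      epochs = epochs, n = n, fs = fs, epoch_len_s = epoch_len_s,
      increment = inc, start_times_s = (starts - 1L) / fs, channel = channel
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs of %g s (%d samples, %d-sample step) @ %g Hz [%s]\n",
    nrow(x$epochs), x$epoch_len_s, x$n, x$increment, x$fs, x$channel
  ))
  invisible(x)
}

#' Default preprocessing / pipeline configuration
#'
#' One list holding every tunable used across the pipeline, suitable for
#' serialization next to reports.
#'
#' @param ... named overrides of the defaults.
#' @return A named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    band_low_hz = 0.5, band_high_hz = 29, butter_order = 2,
    notch_hz = 60, notch_q = 30, apply_filters = TRUE,
    epoch_len_s = 1, order_m = 5, svd_tol = 1e-12, instability_tol = 1e-6,
    classifier = "decision_tree", cv_folds = 10, seed = 20240316,
    window_s = 30, fusion = "majority"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  cfg
}
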