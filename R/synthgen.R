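#' Specify an innovations-form linear system for oracle signals
#'
#' Defines the generating system `x[T+1] = A x[T] + K e[T]`,
#' `y[T] = C x[T] + e[T]` with Gaussian innovations of standard deviation
#' `sd` (`sd = 0` gives the deterministic free run used for
#' parameter-recovery oracles).
#'
#' @param A state matrix (r x r), spectral radius < 1 unless
#'   `allow_unstable`.
#' @param C output row (length r).
#' @param K gain column (length r).
#' @param x0 initial state (length r).
#' @param sd innovation standard deviation.
#' @param n output length in samples.
#' @param seed RNG seed for the innovations.
#' @param allow_unstable set to simulate an unstable spec deliberately.
#' @return A `linear_system_spec` list.
#' @export
linear_system_spec <- function(A, C, K = NULL, x0 = NULL, sd = 0, n = 1000,
                               seed = 1, allow_unstable = FALSE) {
  A <- as.matrix(A)
  r <- nrow(A)
  stopifnot(ncol(A) == r, length(C) == r)
  if (is.null(K)) K <- rep(0, r)
  if (is.null(x0)) x0 <- rep(1, r)
  stopifnot(length(K) == r, length(x0) == r)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1 && !allow_unstable) {
    abort(sprintf("Unstable system (spectral radius %.3f); pass allow_unstable = TRUE to override.", rho))
  }
  structure(list(r = r, A = A, C = as.numeric(C), K = as.numeric(K),
                 x0 = as.numeric(x0), sd = sd, n = as.integer(n),
                 seed = seed),
            class = "linear_system_spec")
}

#' Simulate the output of a linear system spec
#'
#' Exact recursion of the innovations model; a pure function of the spec
#' (the seed included), so identical specs give identical outputs.
#'
#' @param spec a [linear_system_spec()].
#' @return Numeric vector of length `spec$n`.
#' @export
#' @examples
#' s <- linear_system_spec(A = matrix(0.9), C = 1, x0 = 1, n = 10)
#' gen_linear_output(s)  # 0.9^(0:9)
gen_linear_output <- function(spec) {
  stopifnot(inherits(spec, "linear_system_spec"))
  e <- if (spec$sd > 0) {
    withr::with_seed(spec$seed, rnorm(spec$n, sd = spec$sd))
  } else {
    rep(0, spec$n)
  }
  y <- numeric(spec$n)
  x <- spec$x0
  for (t in seq_len(spec$n)) {
    y[t] <- sum(spec$C * x) + e[t]
    x <- as.numeric(spec$A %*% x + spec$K * e[t])
  }
  y
}

#' Random stable system spec
#'
#' Draws `r` poles (real or conjugate pairs) with moduli in `radius`,
#' builds the real companion-form state matrix, and draws `C`, `K`, `x0`
#' from standard normals. Deterministic in `seed`.
#'
#' @param r system order.
#' @param seed RNG seed.
#' @param radius modulus range for the poles.
#' @param sd innovation standard deviation for the spec.
#' @param n output length.
#' @return A [linear_system_spec()] with a `poles` attribute (the complex
#'   eigenvalues of `A`).
#' @export
random_stable_system <- function(r, seed = 1, radius = c(0.5, 0.95),
                                 sd = 0, n = 1000) {
  withr::with_seed(seed, {
    poles <- complex(0)
    while (length(poles) < r) {
      mod <- runif(1, radius[1], radius[2])
      if (r - length(poles) >= 2 && runif(1) < 0.7) {
        th <- runif(1, 0.05, pi - 0.05)
        poles <- c(poles, complex(modulus = mod, argument = th),
                   complex(modulus = mod, argument = -th))
      } else {
        poles <- c(poles, complex(real = mod * sign(runif(1, -1, 1))))
      }
    }
    # companion matrix of the real characteristic polynomial
    cf <- Re(coef_from_roots(poles))
    A <- rbind(-cf[-1], cbind(diag(r - 1), rep(0, r - 1)))
    if (r == 1) A <- matrix(-cf[2], 1, 1)
    spec <- linear_system_spec(A, C = rnorm(r), K = rnorm(r), x0 = rnorm(r),
                               sd = sd, n = n, seed = seed)
    attr(spec, "poles") <- poles
    spec
  })
}

# monic polynomial coefficients (descending powers) from its roots
coef_from_roots <- function(roots) {
  cf <- 1
  for (rt in roots) cf <- c(cf, 0) - c(0, cf * rt)
  cf
}

#' Specify a synthetic scalp-EEG recording
#'
#' Defaults describe a plausible desk-scale recording: 19-channel 10--20
#' montage at 256 Hz, ten minutes long, with two annotated
#' electrographic seizures. Background is 1/f-shaped noise plus a 10 Hz
#' posterior rhythm; ictal segments are spike-wave trains whose fundamental
#' chirps upward from about 3 Hz with an amplitude ramp, superposed on the
#' background.
#'
#' @param fs sampling rate in Hz (>= 100).
#' @param duration_s recording length in seconds.
#' @param channels number of channels.
#' @param seizures data frame with `onset_s`, `offset_s` (non-overlapping).
#' @param background_uV background RMS amplitude in microvolts.
#' @param alpha_hz frequency of the background rhythm.
#' @param ictal_f0,ictal_f1 start and end of the ictal fundamental chirp in
#'   Hz.
#' @param ictal_amp_mult peak ictal amplitude as a multiple of the
#'   background RMS.
#' @param seed RNG seed; all generated content is a pure function of the
#'   spec.
#' @return A `synth_recording_spec` list.
#' @export
synth_recording_spec <- function(fs = 256, duration_s = 600, channels = 19,
                                 seizures = data.frame(
                                   onset_s = c(120, 400),
                                   offset_s = c(160, 450)
                                 ),
                                 background_uV = 30, alpha_hz = 10,
                                 ictal_f0 = 3, ictal_f1 = 8,
                                 ictal_amp_mult = 4, seed = 1) {
  if (fs < 100) abort("Sampling rate must be at least 100 Hz.")
  seizures <- as.data.frame(seizures)
  if (nrow(seizures) > 0) {
    o <- order(seizures$onset_s)
    seizures <- seizures[o, , drop = FALSE]
    if (any(seizures$onset_s >= seizures$offset_s)) {
      abort("Seizure intervals need onset < offset.")
    }
    if (any(seizures$onset_s < 0) ||
        any(seizures$offset_s > duration_s)) {
      abort("Seizure intervals must lie within the recording.")
    }
    if (nrow(seizures) > 1 &&
        any(seizures$onset_s[-1] < seizures$offset_s[-nrow(seizures)])) {
      abort("Seizure intervals must not overlap.")
    }
  }
  structure(list(fs = fs, duration_s = duration_s, channels = channels,
                 seizures = seizures, background_uV = background_uV,
                 alpha_hz = alpha_hz, ictal_f0 = ictal_f0,
                 ictal_f1 = ictal_f1, ictal_amp_mult = ictal_amp_mult,
                 seed = seed),
            class = "synth_recording_spec")
}

# 1/f-shaped Gaussian noise via spectral shaping, unit RMS
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # two-sided frequency index
  shape <- 1 / sqrt(pmax(f, 1))
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate background (interictal) EEG
#'
#' Per-channel 1/f-shaped Gaussian noise plus a sinusoidal rhythm at
#' `alpha_hz` with channel-specific random phase, scaled to the spec's RMS
#' amplitude, zero mean. Bitwise reproducible from the spec seed.
#'
#' @param spec a [synth_recording_spec()].
#' @return Channels-by-samples matrix in microvolts.
#' @export
gen_background <- function(spec) {
  stopifnot(inherits(spec, "synth_recording_spec"))
  n <- as.integer(round(spec$fs * spec$duration_s))
  withr::with_seed(spec$seed, {
    t <- (seq_len(n) - 1) / spec$fs
    sig <- matrix(0, spec$channels, n)
    for (ch in seq_len(spec$channels)) {
      base <- pink_noise(n)
      alpha <- sin(2 * pi * spec$alpha_hz * t + runif(1, 0, 2 * pi))
      x <- base + 0.7 * alpha
      sig[ch, ] <- spec$background_uV * (x - mean(x)) / sqrt(mean(x^2))
    }
    sig
  })
}

#' Generate one ictal (seizure) segment
#'
#' A spike-wave train whose fundamental frequency chirps linearly from
#' `ictal_f0` to `ictal_f1` Hz over the segment, with sharpened periodic
#' spikes and an amplitude ramp, to be superposed on the background. A
#' zero-length interval yields an empty matrix.
#'
#' @param spec a [synth_recording_spec()].
#' @param onset,offset segment bounds in seconds.
#' @return Channels-by-samples matrix patch in microvolts.
#' @export
gen_seizure_segment <- function(spec, onset, offset) {
  stopifnot(inherits(spec, "synth_recording_spec"))
  d <- offset - onset
  n <- as.integer(round(spec$fs * d))
  if (n <= 0) return(matrix(0, spec$channels, 0))
  t <- (seq_len(n) - 1) / spec$fs
  # linear chirp phase: f(t) = f0 + (f1 - f0) t / d
  phase <- 2 * pi * (spec$ictal_f0 * t +
                       (spec$ictal_f1 - spec$ictal_f0) * t^2 / (2 * d))
  wave <- sin(phase)
  spikes <- (exp(2.5 * cos(phase)) - exp(-2.5)) / (exp(2.5) - exp(-2.5))
  morph <- 0.5 * wave + spikes
  morph <- morph - mean(morph)
  morph <- morph / sqrt(mean(morph^2))   # unit RMS before scaling
  ramp <- seq(0.6, 1, length.out = n)
  amp <- spec$ictal_amp_mult * spec$background_uV
  withr::with_seed(spec$seed + as.integer(round(onset)), {
    gains <- runif(spec$channels, 0.8, 1.2)
  })
  outer(gains, amp * ramp * morph)
}

#' Generate a complete synthetic recording with annotations
#'
#' Background EEG with ictal segments added over the annotated intervals.
#' The returned annotation set mirrors the spec's intervals exactly.
#'
#' @param spec a [synth_recording_spec()].
#' @param id recording identifier.
#' @return A list with `recording` (an [eeg_recording()]) and `annotations`
#'   (tibble).
#' @export
#' @examples
#' spec <- synth_recording_spec(duration_s = 60, channels = 2,
#'                              seizures = data.frame(onset_s = 20,
#'                                                    offset_s = 40))
#' synth <- gen_recording(spec)
#' synth$annotations
gen_recording <- function(spec, id = paste0("synth-", spec$seed)) {
  stopifnot(inherits(spec, "synth_recording_spec"))
  sig <- gen_background(spec)
  if (nrow(spec$seizures) > 0) {
    for (s in seq_len(nrow(spec$seizures))) {
      on <- spec$seizures$onset_s[s]; off <- spec$seizures$offset_s[s]
      patch <- gen_seizure_segment(spec, on, off)
      i0 <- as.integer(round(on * spec$fs)) + 1L
      idx <- i0:(i0 + ncol(patch) - 1L)
      sig[, idx] <- sig[, idx] + patch
    }
  }
  ann <- annotation_set(spec$seizures$onset_s, spec$seizures$offset_s,
                        rep("seizure", nrow(spec$seizures)),
                        duration_s = spec$duration_s)
  list(
    recording = eeg_recording(sig, fs = spec$fs,
                              channel_names = paste0("ch", seq_len(spec$channels)),
                              id = id),
    annotations = ann
  )
}

#' Two-class oracle benchmark feature table
#'
#' A separable benchmark built from the model class itself: one fixed
#' order-3 system per class, class 0 with all pole moduli 0.7 and class 1
#' with pole moduli 0.97 (same pole angles), simulated with a small
#' innovation noise and a fresh random initial state per epoch. The two
#' classes' state-matrix features then differ in their means far beyond the
#' within-class noise scatter, so any reasonable classifier can separate
#' them. Used to validate classifiers and sweeps without clinical data.
#'
#' @param n_per_class epochs per class.
#' @param m model order used for feature extraction.
#' @param n epoch length in samples.
#' @param noise_sd innovation standard deviation of the generating systems.
#' @param seed RNG seed.
#' @return A feature table (tibble) in the [extract_features()] schema with
#'   `recording_id = "benchmark"`.
#' @export
gen_benchmark_features <- function(n_per_class = 60, m = 5, n = 500,
                                   noise_sd = 0.05, seed = 1) {
  rows <- purrr::map_dfr(c(0L, 1L), function(cls) {
    radius <- if (cls == 0L) 0.7 else 0.97
    sys <- benchmark_system(radius = radius, seed = seed)
    purrr::map_dfr(seq_len(n_per_class), function(i) {
      ep_seed <- seed + 1000L * cls + i
      spec <- linear_system_spec(
        sys$A, sys$C, sys$K,
        x0 = withr::with_seed(ep_seed, rnorm(3)),
        sd = noise_sd, n = n, seed = ep_seed
      )
      y <- gen_linear_output(spec)
      mod <- withCallingHandlers(
        estimate_model(y, m = m),
        warning = function(w) invokeRestart("muffleWarning")
      )
      v <- to_feature_vector(mod)
      dplyr::bind_cols(
        tibble(recording_id = "benchmark",
               channel = paste0("class", cls, "_", i),
               t_start_s = 0, m = as.integer(m)),
        as_tibble(setNames(as.list(v), feature_names(m))),
        tibble(fit_pct = mod$fit_pct, label = cls)
      )
    })
  })
  rows
}

# order-3 system with one real pole and a conjugate pair, all at the given
# modulus; pole angle and C/K drawn once from the seed
benchmark_system <- function(radius, seed) {
  withr::with_seed(seed, {
    th <- runif(1, 0.2, 0.6)
    poles <- c(complex(real = radius),
               complex(modulus = radius, argument = c(th, -th)))
    cf <- Re(coef_from_roots(poles))
    A <- rbind(-cf[-1], cbind(diag(2), rep(0, 2)))
    list(A = A, C = rnorm(3), K = rnorm(3))
  })
}
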