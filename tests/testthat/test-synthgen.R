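test_that("a one-pole free run is exactly geometric", {
  s <- linear_system_spec(A = matrix(0.9), C = 1, x0 = 1, n = 20)
  expect_equal(gen_linear_output(s), 0.9^(0:19))
})

test_that("noiseless outputs ignore the seed; noisy outputs honour it", {
  a <- gen_linear_output(linear_system_spec(matrix(0.8), 1, n = 50, seed = 1))
  b <- gen_linear_output(linear_system_spec(matrix(0.8), 1, n = 50, seed = 99))
  expect_identical(a, b)

  s1 <- random_stable_system(3, seed = 5, sd = 0.1, n = 200)
  expect_identical(gen_linear_output(s1), gen_linear_output(s1))
  s2 <- random_stable_system(3, seed = 5, sd = 0.1, n = 200)
  s2$seed <- 6
  expect_false(identical(gen_linear_output(s1), gen_linear_output(s2)))
})

test_that("stationary output variance stays near the Lyapunov solution", {
  spec <- random_stable_system(3, seed = 17, radius = c(0.5, 0.85),
                               sd = 0.1, n = 1000)
  # discrete Lyapunov equation by Kronecker solve: P = A P A' + sd^2 K K'
  r <- spec$r
  Q <- spec$sd^2 * (spec$K %*% t(spec$K))
  P <- matrix(solve(diag(r^2) - kronecker(spec$A, spec$A), as.vector(Q)), r)
  var_oracle <- as.numeric(t(spec$C) %*% P %*% spec$C) + spec$sd^2
  y <- gen_linear_output(spec)
  v <- var(y[200:1000])   # skip the transient from x0
  expect_lt(v, 3 * var_oracle)
  expect_gt(v, var_oracle / 3)
})

test_that("unstable specs are refused unless overridden", {
  expect_error(linear_system_spec(matrix(1.05), 1), "Unstable")
  s <- linear_system_spec(matrix(1.05), 1, n = 10, allow_unstable = TRUE)
  expect_length(gen_linear_output(s), 10)
})

test_that("background has the right shape, size and spectral tilt", {
  spec <- synth_recording_spec(fs = 256, duration_s = 10, channels = 3,
                               seizures = data.frame(onset_s = numeric(0),
                                                     offset_s = numeric(0)),
                               seed = 2)
  bg <- gen_background(spec)
  expect_equal(dim(bg), c(3L, 2560L))
  expect_identical(bg, gen_background(spec))

  # alpha-band power dominates 25-35 Hz power by construction
  pg <- spec.pgram(bg[1, ], plot = FALSE, taper = 0)
  f <- pg$freq * 256
  p_alpha <- mean(pg$spec[f >= 8 & f <= 12])
  p_beta <- mean(pg$spec[f >= 25 & f <= 35])
  expect_gt(p_alpha, p_beta)
  expect_lt(abs(mean(bg[1, ])), 1)
})

test_that("ictal segments chirp upward and stand above background", {
  spec <- synth_recording_spec(seed = 3)
  patch <- gen_seizure_segment(spec, 100, 140)
  expect_equal(dim(patch), c(19L, 40L * 256L))

  zc <- function(x) sum(diff(sign(x - mean(x))) != 0)
  n <- ncol(patch)
  first_q <- patch[1, 1:(n %/% 4)]
  last_q <- patch[1, (3 * n %/% 4):n]
  expect_gt(zc(last_q), zc(first_q))

  bg_rms <- spec$background_uV
  expect_gt(sqrt(mean(patch[1, ]^2)), 2 * bg_rms)

  empty <- gen_seizure_segment(spec, 100, 100)
  expect_equal(ncol(empty), 0L)
})

test_that("generated recordings mirror their spec and are reproducible", {
  spec <- synth_recording_spec(fs = 128, duration_s = 120, channels = 2,
                               seizures = data.frame(
                                 onset_s = c(30, 80), offset_s = c(50, 100)),
                               seed = 9)
  synth <- gen_recording(spec)
  expect_s3_class(synth$recording, "eeg_recording")
  expect_equal(nrow(synth$annotations), 2L)
  expect_equal(synth$annotations$onset_s, c(30, 80))
  expect_equal(synth$annotations$offset_s, c(50, 100))

  again <- gen_recording(spec)
  expect_identical(synth$recording$signals, again$recording$signals)

  expect_error(synth_recording_spec(
    seizures = data.frame(onset_s = c(10, 20), offset_s = c(25, 40))),
    "overlap")
})

test_that("pole recovery error shrinks with the innovation noise level", {
  # The raw-sample Hankel realization keys on the deterministic transient,
  # so its pole error is governed by the noise level, vanishing at sd = 0.
  mean_err <- vapply(c(0.1, 0.02, 0), function(sdv) {
    errs <- vapply(1:25, function(seed) {
      spec <- random_stable_system(2, seed = seed, radius = c(0.85, 0.95),
                                   sd = sdv, n = 1000)
      y <- gen_linear_output(spec)
      mod <- suppressWarnings(estimate_model(y, m = 2))
      pole_match_error(eigen(mod$A, only.values = TRUE)$values,
                       attr(spec, "poles"))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mean_err[2], mean_err[1])
  expect_lt(mean_err[3], 1e-6)
})
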