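test_that("Hankel pair indexes the epoch exactly as the shift structure demands", {
  hp <- build_hankel_pair(as.numeric(1:10), m = 2)
  expect_equal(dim(hp$H0), c(4L, 6L))
  expect_equal(hp$H0[1, ], as.numeric(1:6))
  expect_equal(hp$H0[4, ], as.numeric(4:9))
  expect_equal(hp$H1, hp$H0 + 1)
  # anti-diagonal constancy and the one-step shift relation
  for (i in 1:3) {
    expect_equal(hp$H0[i + 1, 1:5], hp$H0[i, 2:6])
    expect_equal(hp$H1[i, ], hp$H0[i + 1, ])
  }

  hp5 <- build_hankel_pair(rnorm(1000), m = 5)
  expect_equal(dim(hp5$H0), c(10L, 990L))

  expect_equal(qr(build_hankel_pair(rep(3, 50), m = 2)$H0)$rank, 1L)
  expect_error(build_hankel_pair(rnorm(20), m = 5), "n > 4m")
})

test_that("a geometric epoch realizes to its exact one-pole system", {
  y <- 0.9^(0:99)
  mod <- realize(build_hankel_pair(y, m = 1))
  expect_equal(as.numeric(mod$A), 0.9, tolerance = 1e-10)
})

test_that("a damped cosine realizes to its known conjugate pole pair", {
  t <- 1:400
  y <- 0.95^t * cos(0.3 * t)
  mod <- estimate_model(y, m = 2)
  est <- eigen(mod$A, only.values = TRUE)$values
  truth <- complex(modulus = 0.95, argument = c(0.3, -0.3))
  expect_lt(pole_match_error(est, truth), 1e-6)
  expect_gt(mod$fit_pct, 99.9)
})

test_that("estimated realization matches the brute-force route on free runs", {
  spec <- random_stable_system(3, seed = 11, radius = c(0.85, 0.97))
  y <- gen_linear_output(spec)
  est <- realize(build_hankel_pair(y, m = 3))
  orc <- oracle_realize(y, m = 3)
  mk_est <- markov_parameters(est, 20)
  mk_orc <- oracle_markov(orc, 20)
  expect_lt(max(abs(mk_est - mk_orc)), 1e-8 * max(1, max(abs(mk_orc))))
  expect_lt(
    pole_match_error(eigen(est$A, only.values = TRUE)$values,
                     eigen(orc$A, only.values = TRUE)$values),
    1e-8
  )
})

test_that("free-run simulation reproduces data generated at the exact order", {
  y <- 0.9^(0:199)
  mod <- list(m = 1L, A = matrix(0.9), C = matrix(1, 1), K = matrix(0.1))
  class(mod) <- "ss_realization"
  expect_equal(simulate_output(mod, y), y, ignore_attr = TRUE,
               tolerance = 1e-12)

  nil <- list(m = 2L, A = matrix(0, 2, 2), C = matrix(c(1, 2), 1),
              K = matrix(0, 2))
  class(nil) <- "ss_realization"
  ys <- simulate_output(nil, c(5, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(ys[1], 5, ignore_attr = TRUE)
  expect_equal(ys[-1], rep(0, 9), ignore_attr = TRUE)

  spec <- random_stable_system(3, seed = 4, radius = c(0.9, 0.97), n = 600)
  y3 <- gen_linear_output(spec)
  mod3 <- estimate_model(y3, m = 3)
  ysim <- suppressWarnings(simulate_output(mod3, y3))
  expect_lt(max(abs(ysim - y3)), 1e-6 * max(abs(y3)))
})

test_that("the fit score behaves as a normalized RMSE in percent", {
  y <- rnorm(100)
  expect_equal(fit_nrmse(y, y), 100)
  expect_equal(fit_nrmse(y, rep(mean(y), 100)), 0)
  alt <- rep(c(1, -1), 50)
  expect_equal(fit_nrmse(alt, rep(0, 100)), 0)
  expect_warning(out <- fit_nrmse(rep(2, 10), rnorm(10)), "constant")
  expect_true(is.na(out))
  # never exceeds 100, and 100 only for exact reproduction
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- rnorm(50); b <- a + rnorm(50, sd = 0.1)
    })
    expect_lt(fit_nrmse(a, b), 100)
  }
})

test_that("estimate_model recovers noiseless data at the exact order", {
  spec <- random_stable_system(5, seed = 21, radius = c(0.9, 0.98), n = 1000)
  y <- gen_linear_output(spec)
  mod <- estimate_model(y, m = 5)
  expect_gt(mod$fit_pct, 99.9)
  expect_equal(dim(mod$A), c(5L, 5L))
  expect_equal(dim(mod$C), c(1L, 5L))
  expect_equal(dim(mod$K), c(5L, 1L))
  expect_length(mod$singular_values, 10L)
  expect_true(all(diff(mod$singular_values) <= 1e-12))

  wn <- withr::with_seed(2, rnorm(1000))
  mod_wn <- suppressWarnings(estimate_model(wn, m = 5))
  expect_lt(mod_wn$fit_pct, 100)
})

test_that("trailing singular values collapse for low-order noiseless data", {
  spec <- random_stable_system(2, seed = 31, radius = c(0.9, 0.96), n = 800)
  y <- gen_linear_output(spec)
  mod <- suppressWarnings(estimate_model(y, m = 5))
  sv <- mod$singular_values
  expect_lt(sv[3] / sv[1], 1e-8)
})

test_that("amplitude scaling leaves the state matrix invariant", {
  spec <- random_stable_system(3, seed = 41, radius = c(0.85, 0.95), n = 600)
  y <- gen_linear_output(spec)
  m1 <- estimate_model(y, m = 3)
  m2 <- estimate_model(7 * y, m = 3)
  expect_lt(
    pole_match_error(eigen(m1$A, only.values = TRUE)$values,
                     eigen(m2$A, only.values = TRUE)$values),
    1e-8
  )
  # Hankel entries scale linearly, so C and K each pick up sqrt(s) and the
  # Markov sequence scales like the data
  expect_equal(markov_parameters(m2, 10), 7 * markov_parameters(m1, 10),
               tolerance = 1e-7)
})

test_that("a degenerate Hankel matrix is flagged, not fatal", {
  y <- 0.9^(0:199)  # rank-1 data forced to order 3
  expect_warning(mod <- realize(build_hankel_pair(y, m = 3)), "degenerate")
  expect_true(mod$degenerate)
  expect_true(all(is.finite(mod$A)))
})
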