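# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: the realization oracle goes through an
# eigendecomposition of H0 H0' (not svd()), the filter oracle evaluates the
# closed-form transfer-function magnitude, and window/epoch counts come from
# brute-force enumeration.

# Brute-force Ho-Kalman realization from an epoch: eigen route.
oracle_realize <- function(epoch, m) {
  n <- length(epoch)
  q <- n - 2L * m
  idx <- outer(seq_len(2L * m), seq_len(q), `+`) - 1L
  H0 <- matrix(epoch[idx], 2L * m, q)
  H1 <- matrix(epoch[idx + 1L], 2L * m, q)
  eg <- eigen(H0 %*% t(H0), symmetric = TRUE)
  sig <- sqrt(pmax(eg$values[seq_len(m)], 0))
  Rm <- eg$vectors[, seq_len(m), drop = FALSE]
  Sm <- t(H0) %*% Rm %*% diag(1 / sig, m)
  A <- diag(1 / sqrt(sig), m) %*% t(Rm) %*% H1 %*% Sm %*% diag(1 / sqrt(sig), m)
  list(m = m, A = A, C = matrix(Rm[1, ] * sqrt(sig), 1),
       K = matrix(sqrt(sig) * Sm[1, ], ncol = 1))
}

oracle_markov <- function(model, k = 20) {
  out <- numeric(k)
  v <- model$K
  for (i in seq_len(k)) {
    out[i] <- as.numeric(model$C %*% v)
    v <- model$A %*% v
  }
  out
}

# Greedy complex matching: worst-case distance after pairing each estimated
# pole with its nearest remaining true pole.
pole_match_error <- function(est, truth) {
  est <- as.complex(est); truth <- as.complex(truth)
  stopifnot(length(est) == length(truth))
  err <- 0
  for (x in est) {
    i <- which.min(Mod(truth - x))
    err <- max(err, Mod(truth[i] - x))
    truth <- truth[-i]
  }
  err
}

# |B(e^{-iw}) / A(e^{-iw})| for a digital filter at frequency f (Hz).
filter_mag <- function(flt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  b <- flt$b; a <- flt$a
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

# Amplitude of a (near-)sinusoidal signal from the RMS of its central half.
central_amplitude <- function(x) {
  n <- length(x)
  mid <- x[floor(n / 4):ceiling(3 * n / 4)]
  sqrt(2 * mean(mid^2))
}

# Brute-force count of full epochs at increment floor(n/2).
enumerate_epochs <- function(L, n) {
  inc <- n %/% 2
  count <- 0L
  s <- 1L
  while (s + n - 1L <= L) {
    count <- count + 1L
    s <- s + inc
  }
  count
}

# Free-run output of an order-r system given complex poles (via companion
# form), independent of the package generator.
free_run_from_poles <- function(poles, n, seed = 1) {
  r <- length(poles)
  cf <- 1
  for (rt in poles) cf <- c(cf, 0) - c(0, cf * rt)
  cf <- Re(cf)
  A <- if (r == 1) matrix(-cf[2], 1, 1) else {
    rbind(-cf[-1], cbind(diag(r - 1), rep(0, r - 1)))
  }
  withr::with_seed(seed, {
    C <- rnorm(r); x <- rnorm(r)
  })
  y <- numeric(n)
  for (t in seq_len(n)) {
    y[t] <- sum(C * x)
    x <- as.numeric(A %*% x)
  }
  y
}
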