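#' Build the shifted pair of block Hankel matrices for one epoch
#'
#' For an epoch `y_1..y_n` and model order `m`, builds the `2m x (n - 2m)`
#' Hankel matrices `H0[i, j] = y[i + j - 1]` (samples `1..n-1`) and
#' `H1[i, j] = y[i + j]` (samples `2..n`). The block-row count `2m` is twice
#' the model order; the width `n - 2m` is the largest for which the
#' one-step-shifted matrix still fits inside the epoch.
#'
#' @param epoch numeric vector of length `n > 4m`.
#' @param m model order (>= 1).
#' @return A `hankel_pair`: list with matrices `H0`, `H1` and scalars `m`, `n`.
#' @export
#' @examples
#' hp <- build_hankel_pair(1:10, m = 2)
#' hp$H0[1, ]  # 1 2 3 4 5 6
build_hankel_pair <- function(epoch, m) {
  check_signal(epoch)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    abort("`m` must be a positive integer model order.")
  }
  m <- as.integer(m)
  n <- length(epoch)
  if (n <= 4L * m) {
    abort(sprintf("Epoch too short: need n > 4m (n = %d, m = %d).", n, m))
  }
  q <- n - 2L * m
  idx <- outer(seq_len(2L * m), seq_len(q), `+`) - 1L
  H0 <- matrix(epoch[idx], nrow = 2L * m, ncol = q)
  H1 <- matrix(epoch[idx + 1L], nrow = 2L * m, ncol = q)
  structure(list(H0 = H0, H1 = H1, m = m, n = n), class = "hankel_pair")
}

#' Minimal state-space realization from a Hankel pair
#'
#' SVD-based single-output realization: with `H0 = R S V^T`, the leading `m`
#' singular triplets give the balanced factors, the one-step shift `H1`
#' projected onto them gives the state matrix, and the first row/column of
#' the observability/controllability factors give the output matrix and gain
#' column:
#' \deqn{A = \Sigma_m^{-1/2} R_m^T H_1 S_m \Sigma_m^{-1/2}, \quad
#'       C = e_1^T R_m \Sigma_m^{1/2}, \quad
#'       K = \Sigma_m^{1/2} S_m^T e_1.}
#' If the `m`-th singular value falls below `svd_tol * sigma_1` the model is
#' flagged degenerate and the inverse square roots are regularized.
#'
#' @param hp a [build_hankel_pair()] result.
#' @param svd_tol relative singular-value tolerance for degeneracy.
#' @return An `ss_realization`: list with `m`, `A` (m x m), `C` (1 x m),
#'   `K` (m x 1), `singular_values` (length 2m, descending), `fit_pct`
#'   (`NA` until [estimate_model()] fills it), and flags `degenerate`,
#'   `unstable`.
#' @export
realize <- function(hp, svd_tol = 1e-12) {
  stopifnot(inherits(hp, "hankel_pair"))
  m <- hp$m
  sv <- svd(hp$H0)
  d <- sv$d
  degenerate <- d[m] < svd_tol * d[1] || !is.finite(d[m]) || d[1] == 0
  if (degenerate) {
    warn("realize: Hankel matrix numerically rank-deficient at the requested order; model flagged degenerate.")
  }
  d_reg <- pmax(d[seq_len(m)], svd_tol * max(d[1], .Machine$double.xmin))
  Rm <- sv$u[, seq_len(m), drop = FALSE]
  Sm <- sv$v[, seq_len(m), drop = FALSE]
  s_half <- sqrt(d_reg)
  s_ihalf <- 1 / s_half
  A <- (s_ihalf * (t(Rm) %*% hp$H1 %*% Sm)) %*% diag(s_ihalf, m)
  C <- matrix(Rm[1, ] * s_half, nrow = 1)
  K <- matrix(s_half * Sm[1, ], ncol = 1)
  structure(
    list(
      m = m, A = A, C = C, K = K,
      singular_values = d, fit_pct = NA_real_,
      degenerate = degenerate, unstable = NA
    ),
    class = "ss_realization"
  )
}

#' Free-run simulation of a realization against an epoch
#'
#' Runs the deterministic part of the innovations model,
#' `y_sim[T] = C A^(T-1) x0`, with the initial state chosen by least squares
#' of the epoch onto the observability sequence `(C, CA, CA^2, ...)`. An
#' estimated state matrix with spectral radius beyond `1 + instability_tol`
#' is still simulated but flagged.
#'
#' @param model an `ss_realization`.
#' @param epoch the epoch the model was estimated from (sets the horizon and
#'   the initial state).
#' @param instability_tol spectral-radius slack before flagging.
#' @return Numeric vector `y_sim` the length of `epoch`, with attribute
#'   `unstable`.
#' @export
simulate_output <- function(model, epoch, instability_tol = 1e-6) {
  stopifnot(inherits(model, "ss_realization"))
  check_signal(epoch)
  n <- length(epoch)
  m <- model$m
  rho <- max(Mod(eigen(model$A, only.values = TRUE)$values))
  unstable <- rho > 1 + instability_tol
  if (unstable) {
    warn(sprintf("simulate_output: estimated state matrix is unstable (spectral radius %.4f).", rho))
  }
  O <- matrix(0, nrow = n, ncol = m)
  O[1, ] <- model$C
  for (t in seq_len(n - 1L)) O[t + 1L, ] <- O[t, ] %*% model$A
  keep <- is.finite(rowSums(O))
  x0 <- qr.coef(qr(O[keep, , drop = FALSE]), epoch[keep])
  x0[is.na(x0)] <- 0
  y_sim <- as.numeric(O %*% x0)
  attr(y_sim, "unstable") <- unstable
  y_sim
}

#' Normalized root-mean-square fit, in percent
#'
#' `Fit% = 100 * (1 - RMSE(y, y_sim) / sigma(y))` with `sigma` the
#' population standard deviation of the epoch. 100 means a perfect
#' reproduction; predicting the epoch mean scores 0; worse than the mean
#' goes negative. A constant epoch (`sigma = 0`) has no defined fit and
#' returns `NA` with a warning.
#'
#' @param epoch,y_sim equal-length numeric vectors.
#' @return Fit percentage (scalar, `<= 100`).
#' @export
fit_nrmse <- function(epoch, y_sim) {
  if (length(epoch) != length(y_sim)) abort("epoch and y_sim lengths differ.")
  sigma <- sqrt(mean((epoch - mean(epoch))^2))
  if (sigma == 0) {
    warn("fit_nrmse: constant epoch, fit undefined.")
    return(NA_real_)
  }
  rmse <- sqrt(mean((epoch - y_sim)^2))
  100 * (1 - rmse / sigma)
}

#' Estimate an order-m state-space model for one epoch
#'
#' Composition of [build_hankel_pair()], [realize()], [simulate_output()]
#' and [fit_nrmse()]; the returned realization carries its fit percentage
#' and stability flag.
#'
#' @inheritParams build_hankel_pair
#' @param m model order, typically 3--10 (default 5).
#' @param svd_tol,instability_tol see [realize()] and [simulate_output()].
#' @return An `ss_realization` with `fit_pct` populated.
#' @export
#' @examples
#' y <- 0.95^(0:499) * cos(0.3 * (0:499))
#' mod <- estimate_model(y, m = 2)
#' round(mod$fit_pct, 2)
estimate_model <- function(epoch, m = 5, svd_tol = 1e-12,
                           instability_tol = 1e-6) {
  hp <- build_hankel_pair(epoch, m)
  model <- realize(hp, svd_tol = svd_tol)
  y_sim <- withCallingHandlers(
    simulate_output(model, epoch, instability_tol = instability_tol),
    warning = function(w) invokeRestart("muffleWarning")
  )
  model$unstable <- attr(y_sim, "unstable")
  model$fit_pct <- suppressWarnings(fit_nrmse(epoch, y_sim))
  model
}

#' Markov parameters of a realization
#'
#' The sequence `C A^(k-1) K`, invariant under changes of state basis; two
#' realizations of the same data agree on it regardless of coordinates.
#'
#' @param model an `ss_realization` (or any list with `A`, `C`, `K`).
#' @param k number of parameters to return.
#' @return Numeric vector of length `k`.
#' @export
markov_parameters <- function(model, k = 20) {
  out <- numeric(k)
  v <- model$K
  for (i in seq_len(k)) {
    out[i] <- as.numeric(model$C %*% v)
    v <- model$A %*% v
  }
  out
}

#' @export
print.ss_realization <- function(x, ...) {
  rho <- max(Mod(eigen(x$A, only.values = TRUE)$values))
  cat(sprintf(
    "<ss_realization> order %d | fit %s%% | spectral radius %.4f%s%s\n",
    x$m,
    ifelse(is.na(x$fit_pct), "NA", sprintf("%.2f", x$fit_pct)),
    rho,
    if (isTRUE(x$degenerate)) " | DEGENERATE" else "",
    if (isTRUE(x$unstable)) " | UNSTABLE" else ""
  ))
  invisible(x)
}

#' @describeIn estimate_model broom-style one-row summary of a realization.
#' @param x an `ss_realization`.
#' @param ... unused.
#' @method glance ss_realization
#' @export
glance.ss_realization <- function(x, ...) {
  tibble(
    m = x$m,
    fit_pct = x$fit_pct,
    spectral_radius = max(Mod(eigen(x$A, only.values = TRUE)$values)),
    sigma_ratio = x$singular_values[x$m] / x$singular_values[1],
    degenerate = isTRUE(x$degenerate),
    unstable = isTRUE(x$unstable)
  )
}

#' @describeIn estimate_model eigenvalues of the state matrix, one row each.
#' @method tidy ss_realization
#' @export
tidy.ss_realization <- function(x, ...) {
  ev <- eigen(x$A, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  tibble(
    eigenvalue = seq_along(ev),
    real = Re(ev), imag = Im(ev),
    modulus = Mod(ev), frequency_rad = Arg(ev)
  )
}
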