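# Covariance estimators: plain trace-normalized spatial covariance, banded
# temporal weight matrices (correlation / Euclidean / uniform), their graph
# Laplacians, and Laplacian-weighted normalized covariances.

PSD_RTOL <- 1e-10  # eigenvalues in [-tol * lambda_max, 0) are treated as 0

#' Trace-normalized spatial covariance of one trial
#'
#' Computes `R = X X' / tr(X X')` for a trial matrix `X` (channels x
#' samples). Trace normalization makes trials contribute comparably to a
#' class average regardless of their amplitude; `R` is symmetric, positive
#' semidefinite and has unit trace.
#'
#' @param t An [trial()] object.
#' @return A `cov_estimate` object: list with `R` (N x N matrix) and
#'   `n_trials_averaged = 1`.
#' @export
normalized_covariance <- function(t) {
  stopifnot(inherits(t, "eeg_trial"))
  X <- t$data
  G <- tcrossprod(X)
  tr <- sum(diag(G))
  if (tr <= 0)
    stop_degenerate("trial is identically zero: tr(XX') = 0")
  cov_estimate(G / tr, n_trials_averaged = 1L)
}

cov_estimate <- function(R, n_trials_averaged) {
  structure(list(R = symmetrize(R),
                 n_trials_averaged = as.integer(n_trials_averaged)),
            class = "cov_estimate")
}

#' @export
print.cov_estimate <- function(x, ...) {
  cat("cov_estimate:", nrow(x$R), "x", ncol(x$R),
      "(average of", x$n_trials_averaged, "trial(s), unit trace)\n")
  invisible(x)
}

new_temporal_weights <- function(W, tau, kind, sigma = NA_real_) {
  structure(list(W = W, tau = as.integer(tau), kind = kind,
                 sigma = as.numeric(sigma)),
            class = "temporal_weights")
}

#' @export
print.temporal_weights <- function(x, ...) {
  cat("temporal_weights:", nrow(x$W), "x", ncol(x$W), "kind =", x$kind,
      "tau =", x$tau,
      if (!is.na(x$sigma)) paste("sigma =", signif(x$sigma, 4)) else "", "\n")
  invisible(x)
}

# Fill a symmetric banded matrix from per-lag weight vectors.
# band_fun(lag) must return the length-(S-lag) vector of weights at |l-m|=lag.
banded_matrix <- function(S, tau, band_fun) {
  W <- matrix(0, S, S)
  for (lag in 0:(tau - 1L)) {
    if (lag >= S) break
    w <- band_fun(lag)
    idx <- seq_len(S - lag)
    W[cbind(idx, idx + lag)] <- w
    W[cbind(idx + lag, idx)] <- w
  }
  W
}

# Per-lag weight vectors of the banded weight matrix (lag 0 .. tau-1),
# without materializing the S x S matrix.
lag_weights <- function(t, kind, tau, sigma = NA) {
  X <- t$data
  S <- ncol(X)
  tau <- check_tau(tau, S)
  if (kind == "correlation") {
    cm <- colMeans(X)
    Xc <- sweep(X, 2L, cm)
    ss <- colSums(Xc^2)
  }
  lapply(0:(min(tau, S) - 1L), function(lag) {
    i <- seq_len(S - lag)
    switch(kind,
      correlation = {
        if (lag == 0L) return(rep(exp(1), S))
        num <- colSums(Xc[, i, drop = FALSE] * Xc[, i + lag, drop = FALSE])
        den <- sqrt(ss[i] * ss[i + lag])
        r <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
        exp(pmin(pmax(r, -1), 1))
      },
      euclidean = {
        if (lag == 0L) return(rep(1, S))
        d2 <- colSums((X[, i, drop = FALSE] - X[, i + lag, drop = FALSE])^2)
        exp(-d2 / sigma)
      },
      uniform = rep(1, S - lag))
  })
}

# Gram matrix X L X' from per-lag weights: X D X' - X W X', accumulated
# lag by lag so no dense S x S matrix is ever formed. Identical (to
# rounding) to X %*% laplacian(W)$L %*% t(X).
gram_from_lag_weights <- function(X, lw) {
  S <- ncol(X); N <- nrow(X)
  d <- numeric(S)
  XW <- matrix(0, N, N)
  for (k in seq_along(lw)) {
    lag <- k - 1L
    w <- lw[[k]]
    i <- seq_len(S - lag)
    d[i] <- d[i] + w
    Aw <- X[, i, drop = FALSE] * rep(w, each = N)
    if (lag == 0L) {
      XW <- XW + tcrossprod(Aw, X[, i, drop = FALSE])
    } else {
      d[i + lag] <- d[i + lag] + w
      C <- tcrossprod(Aw, X[, i + lag, drop = FALSE])
      XW <- XW + C + t(C)
    }
  }
  XD <- X %*% (d * t(X))
  symmetrize(XD - XW)
}

#' Banded correlation temporal weight matrix
#'
#' The weight between time points `l` and `m` inside the local temporal
#' range `tau` is `exp(corr(x_l, x_m))`, where `x_l`, `x_m` are the
#' N-channel sample vectors at those time points and `corr` is the Pearson
#' correlation across channels; outside the band (`|l - m| >= tau`) the
#' weight is 0. In-band weights therefore lie in `[exp(-1), exp(1)]` and
#' the diagonal is `exp(1)`. If either sample vector is constant across
#' channels the correlation is undefined; it is taken as 0 (neutral weight
#' `exp(0) = 1`), which neither attracts nor suppresses the pair.
#'
#' Because the Pearson correlation is invariant to adding a constant to
#' every channel, these weights are unaffected by transient baseline
#' shifts that hit all channels equally — the property that distinguishes
#' them from Euclidean-distance weights ([euclidean_weights()]).
#'
#' @param t An [trial()] object.
#' @param tau Local temporal range in samples (`1 <= tau <= S`).
#' @return A `temporal_weights` object (fields `W`, `tau`, `kind`).
#' @export
correlation_weights <- function(t, tau) {
  stopifnot(inherits(t, "eeg_trial"))
  S <- ncol(t$data)
  tau <- check_tau(tau, S)
  lw <- lag_weights(t, "correlation", tau)
  W <- banded_matrix(S, tau, function(lag) lw[[lag + 1L]])
  new_temporal_weights(W, tau, "correlation")
}

#' Banded Euclidean (Gaussian-kernel) temporal weight matrix
#'
#' The weight between in-band time points is
#' `exp(-||x_l - x_m||^2 / sigma)`; outside the band it is 0. Weights lie
#' in `(0, 1]` with a unit diagonal. Unlike [correlation_weights()], a
#' constant offset added to every channel of one sample vector drives the
#' weight towards 0 as the offset grows.
#'
#' @inheritParams correlation_weights
#' @param sigma Positive kernel scale; see [sigma0()] for the conventional
#'   data-driven choice `sigma = 7 * sigma0(train)`.
#' @return A `temporal_weights` object (fields `W`, `tau`, `kind`, `sigma`).
#' @export
euclidean_weights <- function(t, tau, sigma) {
  stopifnot(inherits(t, "eeg_trial"))
  if (!is_scalar_number(sigma) || sigma <= 0)
    stop_validation("sigma must be a positive number")
  S <- ncol(t$data)
  tau <- check_tau(tau, S)
  lw <- lag_weights(t, "euclidean", tau, sigma = sigma)
  W <- banded_matrix(S, tau, function(lag) lw[[lag + 1L]])
  new_temporal_weights(W, tau, "euclidean", sigma = sigma)
}

#' Uniform temporal weight matrix
#'
#' All in-band weights equal 1. With a full band (`tau = S`) the induced
#' Laplacian-weighted covariance reduces to the centered, trace-normalized
#' covariance, which connects the weighted estimators back to plain CSP.
#'
#' @param S Number of samples.
#' @param tau Local temporal range in samples.
#' @return A `temporal_weights` object.
#' @export
uniform_weights <- function(S, tau) {
  tau <- check_tau(tau, S)
  W <- banded_matrix(S, tau, function(lag) rep(1, S - lag))
  new_temporal_weights(W, tau, "uniform")
}

check_tau <- function(tau, S) {
  if (!is_scalar_number(tau) || tau < 1 || tau != round(tau))
    stop_validation("tau must be a positive integer, got ", tau)
  if (tau > S)
    stop_validation("tau (", tau, ") exceeds the trial length S = ", S)
  as.integer(tau)
}

#' Scale statistic for Euclidean temporal weights
#'
#' Returns the population standard deviation of the squared Euclidean
#' norms of all time-sample vectors pooled across every trial of the
#' training set. The conventional Euclidean kernel scale is
#' `sigma = 7 * sigma0(train)`.
#'
#' @param train A [trial_set()].
#' @return A nonnegative scalar; 0 when all squared norms are identical
#'   (callers must reject a zero kernel scale).
#' @export
sigma0 <- function(train) {
  stopifnot(inherits(train, "trial_set"))
  sq <- unlist(lapply(train$trials, function(t) colSums(t$data^2)),
               use.names = FALSE)
  if (length(sq) < 2L)
    stop_validation("need at least 2 time-sample vectors to compute sigma0")
  m <- mean(sq)
  sqrt(mean((sq - m)^2))   # population (1/n) convention
}

#' Graph Laplacian of a temporal weight matrix
#'
#' `L = D - W` with `D` the diagonal matrix of row sums of `W`. For any
#' symmetric nonnegative `W`, `L` is symmetric positive semidefinite and
#' annihilates the constant vector (`L 1 = 0`).
#'
#' @param w A `temporal_weights` object (or plain symmetric nonnegative
#'   matrix).
#' @return A `temporal_laplacian` object: list with `L` and the row-sum
#'   vector `d`.
#' @export
laplacian <- function(w) {
  W <- if (inherits(w, "temporal_weights")) w$W else w
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop_validation("weight matrix must be square")
  if (any(W < 0))
    stop_validation("weight matrix must be nonnegative")
  if (max(abs(W - t(W))) > 1e-12 * max(1, max(abs(W))))
    stop_validation("weight matrix must be symmetric")
  d <- rowSums(W)
  L <- -W
  diag(L) <- diag(L) + d
  structure(list(L = symmetrize(L), d = d), class = "temporal_laplacian")
}

#' @export
print.temporal_laplacian <- function(x, ...) {
  cat("temporal_laplacian:", nrow(x$L), "x", ncol(x$L), "\n")
  invisible(x)
}

#' Laplacian-weighted trace-normalized covariance of one trial
#'
#' Computes `R = X L X' / tr(X L X')`, the locally temporally weighted
#' analogue of [normalized_covariance()]. The quadratic form `X L X'`
#' equals the weighted pairwise-difference sum
#' `1/2 * sum_lm W_lm (x_l - x_m)(x_l - x_m)'` (the 1/2S scalar of the
#' unweighted identity cancels under trace normalization).
#'
#' @param t An [trial()] object.
#' @param L A `temporal_laplacian` from [laplacian()].
#' @return A `cov_estimate` with unit trace.
#' @export
weighted_covariance <- function(t, L) {
  stopifnot(inherits(t, "eeg_trial"), inherits(L, "temporal_laplacian"))
  X <- t$data
  if (ncol(X) != nrow(L$L))
    stop_validation("Laplacian size (", nrow(L$L),
                    ") does not match trial length (", ncol(X), ")")
  G <- symmetrize(X %*% L$L %*% t(X))
  tr <- sum(diag(G))
  if (tr <= 1e-12 * max(1, sum(X^2)))
    stop_degenerate("tr(X L X') ~ 0: signal is constant in time under ",
                    "these weights (tau = 1 degenerate band?)")
  cov_estimate(G / tr, n_trials_averaged = 1L)
}

#' Class-average covariance estimate
#'
#' Arithmetic mean of the per-trial unit-trace covariance estimates of one
#' class; the mean of unit-trace matrices has unit trace.
#'
#' @param ts A [trial_set()].
#' @param class_label 1 or 2.
#' @param estimator Function mapping an [trial()] to a `cov_estimate`
#'   (default [normalized_covariance()]); supply a closure over a
#'   Laplacian-building step for the weighted variants.
#' @return A `cov_estimate` with `n_trials_averaged` set to the class count.
#' @export
average_covariance <- function(ts, class_label,
                               estimator = normalized_covariance) {
  stopifnot(inherits(ts, "trial_set"))
  if (!class_label %in% c(1L, 2L))
    stop_validation("class_label must be 1 or 2")
  idx <- which(ts$labels == class_label)
  if (length(idx) == 0L)
    stop_validation("no trials with class label ", class_label)
  Rs <- lapply(ts$trials[idx], function(t) estimator(t)$R)
  cov_estimate(Reduce(`+`, Rs) / length(Rs),
               n_trials_averaged = length(idx))
}
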