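# Fixture builders shared across test files. Everything is generated in
# code under explicit seeds; nothing is read from disk.

random_trial <- function(N = 4, S = 50, fs = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trial(matrix(rnorm(N * S), N, S), fs = fs)
}

random_trialset <- function(N = 4, S = 50, K = 5, fs = 100, seed = 1) {
  set.seed(seed)
  trials <- lapply(seq_len(2 * K), function(i)
    trial(matrix(rnorm(N * S), N, S), fs = fs))
  trial_set(trials, rep(c(1L, 2L), each = K))
}

# Random symmetric positive definite matrix.
random_pd <- function(N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(N * N), N, N)
  crossprod(A) + diag(0.1, N)
}

# Brute-force weighted pairwise-difference sum:
# 0.5 * sum_lm W_lm (x_l - x_m)(x_l - x_m)'
pairwise_diff_sum <- function(X, W) {
  S <- ncol(X); N <- nrow(X)
  acc <- matrix(0, N, N)
  for (l in seq_len(S)) {
    for (m in seq_len(S)) {
      d <- X[, l] - X[, m]
      acc <- acc + W[l, m] * tcrossprod(d)
    }
  }
  acc / 2
}

# Direct generalized eigenproblem oracle: Rx v = lambda (Rx + Ry) v,
# solved through the non-symmetric eigendecomposition of (Rx+Ry)^{-1} Rx.
generalized_eig_oracle <- function(Rx, Ry) {
  M <- solve(Rx + Ry) %*% Rx
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}

expect_cov_valid <- function(est, tol = 1e-10) {
  R <- est$R
  expect_lt(max(abs(R - t(R))), 1e-12)
  expect_equal(sum(diag(R)), 1, tolerance = 1e-12)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(ev))
}
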