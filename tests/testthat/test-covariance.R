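test_that("normalized covariance matches the explicit per-sample sum", {
  # identity trial: tr = 2, R = I/2
  t0 <- trial(diag(2), fs = 100)
  expect_equal(normalized_covariance(t0)$R, diag(0.5, 2))
  # brute-force oracle: (1/tr) * sum_l x_l x_l'
  tr <- random_trial(4, 50, seed = 21)
  acc <- matrix(0, 4, 4)
  for (l in seq_len(50)) acc <- acc + tcrossprod(tr$data[, l])
  oracle <- acc / sum(diag(acc))
  expect_lt(max(abs(normalized_covariance(tr)$R - oracle)), 1e-12)
  # scale invariance
  tr2 <- trial(tr$data * -3.7, fs = 100)
  expect_lt(max(abs(normalized_covariance(tr2)$R -
                      normalized_covariance(tr)$R)), 1e-12)
  expect_cov_valid(normalized_covariance(tr))
  expect_error(normalized_covariance(trial(matrix(0, 2, 2) + 0, 100)),
               "identically zero")
})

test_that("correlation weights implement exp(corr) on the band", {
  set.seed(22)
  X <- matrix(rnorm(3 * 6), 3, 6)
  # column 4 = column 2 + huge constant on all channels -> corr = 1
  X[, 4] <- X[, 2] + 1e6
  tr <- trial(X, 100)
  W <- correlation_weights(tr, tau = 3)$W
  expect_equal(W[2, 4], exp(1), tolerance = 1e-12)
  # anti-correlated pair: x_m = -x_l with zero channel mean
  Y <- matrix(rnorm(4 * 5), 4, 5)
  Y[, 2] <- Y[, 1] - mean(Y[, 1])
  Y[, 3] <- -Y[, 2]
  Wy <- correlation_weights(trial(Y, 100), tau = 2)$W
  expect_equal(Wy[2, 3], exp(-1), tolerance = 1e-12)
  # perfect linear relation through the origin
  Z <- cbind(c(1, 2, 3), c(2, 4, 6), rnorm(3))
  Wz <- correlation_weights(trial(Z, 100), tau = 2)$W
  expect_equal(Wz[1, 2], exp(1), tolerance = 1e-12)
  # tau = 1: diagonal-only band, W = e I
  W1 <- correlation_weights(tr, tau = 1)$W
  expect_equal(W1, diag(exp(1), 6))
  # zero-variance column -> neutral weight exp(0) = 1
  C <- matrix(rnorm(3 * 4), 3, 4); C[, 2] <- 5
  Wc <- correlation_weights(trial(C, 100), tau = 2)$W
  expect_equal(Wc[1, 2], 1)
  expect_equal(Wc[2, 3], 1)
  expect_error(correlation_weights(tr, tau = 0), "tau")
  expect_error(correlation_weights(tr, tau = 7), "tau")
})

test_that("euclidean weights implement the Gaussian kernel on the band", {
  set.seed(23)
  X <- matrix(rnorm(3 * 5), 3, 5)
  X[, 3] <- X[, 2]  # zero distance -> weight 1
  tr <- trial(X, 100)
  W <- euclidean_weights(tr, tau = 2, sigma = 1.5)$W
  expect_equal(W[2, 3], 1)
  d2 <- sum((X[, 1] - X[, 2])^2)
  expect_equal(W[1, 2], exp(-d2 / 1.5), tolerance = 1e-12)
  # sigma -> Inf limit: all in-band weights -> 1
  Wb <- euclidean_weights(tr, tau = 3, sigma = 1e12)$W
  expect_true(all(abs(Wb[abs(row(Wb) - col(Wb)) < 3] - 1) < 1e-9))
  expect_error(euclidean_weights(tr, tau = 2, sigma = 0), "sigma")
  expect_error(euclidean_weights(tr, tau = 2, sigma = -1), "sigma")
})

test_that("constant channel offsets leave correlation weights fixed but
           drive euclidean weights to zero", {
  set.seed(24)
  X <- matrix(rnorm(5 * 8), 5, 8)
  Wc0 <- correlation_weights(trial(X, 100), 3)$W
  we_seq <- numeric(3)
  consts <- c(10, 1e3, 1e6)
  for (k in seq_along(consts)) {
    Xs <- X
    Xs[, 4] <- Xs[, 4] + consts[k]  # baseline shift on one time point
    Wc1 <- correlation_weights(trial(Xs, 100), 3)$W
    expect_equal(Wc1, Wc0, tolerance = 1e-9)
    we_seq[k] <- euclidean_weights(trial(Xs, 100), 3, sigma = 10)$W[3, 4]
  }
  expect_true(all(diff(we_seq) <= 0))  # decays with the offset
  expect_lt(we_seq[2], 1e-6)           # already negligible at 1e3
  # the shifted pair keeps weight exactly e under correlation
  Xs <- X; Xs[, 4] <- X[, 3] + 1e8
  Wc <- correlation_weights(trial(Xs, 100), 3)$W
  expect_equal(Wc[3, 4], exp(1), tolerance = 1e-12)
})

test_that("weight matrices satisfy band, symmetry and range invariants", {
  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(2:8, 1); S <- sample(5:40, 1); tau <- sample(1:5, 1)
    tr <- random_trial(N, S)
    for (w in list(correlation_weights(tr, tau),
                   euclidean_weights(tr, tau, sigma = runif(1, 0.5, 5)))) {
      W <- w$W
      expect_equal(W, t(W))
      off <- abs(row(W) - col(W)) >= tau
      expect_true(all(W[off] == 0))
      inb <- !off
      expect_true(all(W[inb] >= 0))
      if (w$kind == "correlation") {
        expect_true(all(W[inb] >= exp(-1) - 1e-12 & W[inb] <= exp(1) + 1e-12))
        expect_true(all(abs(diag(W) - exp(1)) < 1e-12))
      } else {
        expect_true(all(W[inb] > 0 & W[inb] <= 1 + 1e-12))
        expect_true(all(diag(W) == 1))
      }
    }
  }
})

test_that("sigma0 is the population sd of pooled squared sample norms", {
  # two columns with squared norms {1, 4}: population sd = 1.5
  t1 <- trial(matrix(c(1, 0, 0, 2), 2, 2), 100)
  ts <- trial_set(list(t1, t1), c(1, 2))
  # pooled over both trials: {1,4,1,4} -> sd still 1.5
  expect_equal(sigma0(ts), 1.5)
  # pooling equals concatenation of all columns
  ts2 <- random_trialset(3, 10, K = 3, seed = 25)
  sq <- unlist(lapply(ts2$trials, function(t) colSums(t$data^2)))
  expect_equal(sigma0(ts2), sqrt(mean((sq - mean(sq))^2)))
  # zero spread
  tc <- trial(matrix(1, 2, 3), 100)
  expect_equal(sigma0(trial_set(list(tc, tc), c(1, 2))), 0)
})

test_that("laplacian has zero row sums, annihilates 1, and is PSD", {
  # hand-computable case: S = 3, tau = 2, all in-band corr = 1
  e <- exp(1)
  W <- matrix(c(e, e, 0, e, e, e, 0, e, e), 3, 3)
  w <- structure(list(W = W, tau = 2L, kind = "uniform", sigma = NA),
                 class = "temporal_weights")
  L <- laplacian(w)
  expect_equal(L$d, c(2 * e, 3 * e, 2 * e))
  expect_equal(L$L, matrix(c(e, -e, 0, -e, 2 * e, -e, 0, -e, e), 3, 3))
  # properties on random nonnegative symmetric W
  for (seed in 1:8) {
    set.seed(seed)
    S <- sample(3:30, 1)
    M <- matrix(runif(S * S), S, S)
    W <- (M + t(M)) / 2
    L <- laplacian(W)
    expect_lt(max(abs(L$L %*% rep(1, S))), 1e-10)
    ev <- eigen(L$L, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
  }
  expect_error(laplacian(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
})

test_that("weighted covariance equals the brute-force pairwise double sum", {
  for (seed in 1:5) {
    tr <- random_trial(4, 12, seed = 30 + seed)
    tau <- sample(2:6, 1)
    w <- correlation_weights(tr, tau)
    L <- laplacian(w)
    est <- weighted_covariance(tr, L)
    oracle <- pairwise_diff_sum(tr$data, w$W)
    oracle <- oracle / sum(diag(oracle))
    expect_lt(max(abs(est$R - oracle)), 1e-10)
    expect_cov_valid(est)
    # scale invariance
    tr2 <- trial(tr$data * 7.3, 100)
    w2 <- correlation_weights(tr2, tau)
    est2 <- weighted_covariance(tr2, laplacian(w2))
    expect_lt(max(abs(est2$R - est$R)), 1e-10)
  }
})

test_that("uniform full-band weights reproduce the centered covariance", {
  tr <- random_trial(5, 30, seed = 41)
  S <- ncol(tr$data)
  w <- uniform_weights(S, tau = S)
  est <- weighted_covariance(tr, laplacian(w))
  Xc <- tr$data - rowMeans(tr$data)
  centered <- tcrossprod(Xc)
  centered <- centered / sum(diag(centered))
  expect_lt(max(abs(est$R - centered)), 1e-10)
})

test_that("the quadratic-form identity for row-centered trials holds", {
  # gamma' X X' gamma = (1/2S) sum_lm (gamma' x_l - gamma' x_m)^2
  for (seed in 1:5) {
    set.seed(50 + seed)
    N <- 4; S <- 15
    X <- matrix(rnorm(N * S), N, S)
    X <- X - rowMeans(X)
    gamma <- rnorm(N)
    z <- drop(gamma %*% X)
    brute <- sum(outer(z, z, `-`)^2) / (2 * S)
    expect_equal(drop(gamma %*% tcrossprod(X) %*% gamma), brute,
                 tolerance = 1e-10)
  }
})

test_that("weighted covariance rejects degenerate inputs", {
  tr <- random_trial(3, 10, seed = 61)
  # tau = 1: W diagonal, L = 0
  L0 <- laplacian(correlation_weights(tr, 1))
  expect_error(weighted_covariance(tr, L0), "degenerate|constant")
  # size mismatch
  L2 <- laplacian(correlation_weights(random_trial(3, 8, seed = 62), 3))
  expect_error(weighted_covariance(tr, L2), "match")
})

test_that("class averages are means of unit-trace estimates", {
  t1 <- trial(diag(c(1, 0)) + 1e-9, 100)  # R ~ diag(1, 0)
  t2 <- trial(diag(c(0, 1)) + 1e-9, 100)
  ts <- trial_set(list(t1, t2), c(1, 1))
  avg <- average_covariance(ts, 1L)
  expect_equal(avg$R, diag(0.5, 2), tolerance = 1e-6)
  expect_equal(avg$n_trials_averaged, 2L)
  # single trial: equals that trial's estimate
  ts2 <- random_trialset(3, 10, K = 1, seed = 63)
  expect_equal(average_covariance(ts2, 2L)$R,
               normalized_covariance(ts2$trials[[2]])$R)
  # unit trace preserved, missing class rejected
  expect_equal(sum(diag(avg$R)), 1, tolerance = 1e-12)
  ts3 <- trial_set(list(t1, t2), c(1, 1))
  expect_error(average_covariance(ts3, 2L), "no trials")
})
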