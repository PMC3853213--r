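# CSP-family spatial filter fitting by simultaneous diagonalization of the
# two class covariance matrices.

#' Simultaneous diagonalization of two class covariances
#'
#' Solves the CSP eigenproblem: with `U, D` the eigendecomposition of
#' `Rx + Ry` and `V` the eigenvector matrix of `D^{-1/2} U' Rx U D^{-1/2}`,
#' the filter matrix is `Gamma = U D^{-1/2} V`. Its columns jointly
#' diagonalize both covariances: `Gamma' (Rx + Ry) Gamma = I` and
#' `Gamma' Rx Gamma = diag(lambda)` with `lambda` the class-X eigenvalues
#' in `[0, 1]`, sorted descending; the class-Y diagonal is `1 - lambda`.
#' Each column is scaled so its largest-magnitude entry is positive, making
#' fits comparable across runs and platforms.
#'
#' @param Rx,Ry `cov_estimate` objects (or plain symmetric PSD matrices)
#'   for class X (label 1) and class Y (label 2).
#' @param cond_tol Relative tolerance below which the smallest eigenvalue
#'   of `Rx + Ry` is considered rank deficient.
#' @return List with `Gamma` (N x N, columns are filters) and `eigvals`
#'   (descending class-X generalized eigenvalues).
#' @export
solve_simultaneous_diag <- function(Rx, Ry, cond_tol = 1e-10) {
  Rx <- if (inherits(Rx, "cov_estimate")) Rx$R else Rx
  Ry <- if (inherits(Ry, "cov_estimate")) Ry$R else Ry
  stopifnot(is.matrix(Rx), is.matrix(Ry), all(dim(Rx) == dim(Ry)))
  Mtot <- symmetrize(Rx + Ry)
  e1 <- eigen(Mtot, symmetric = TRUE)
  if (min(e1$values) <= cond_tol * max(e1$values))
    stop_validation(
      "Rx + Ry is rank deficient (condition ",
      format(max(e1$values) / max(min(e1$values), .Machine$double.xmin),
             digits = 3),
      "); remove linearly dependent channels or enable a ridge (delta > 0)")
  P <- e1$vectors %*% diag(1 / sqrt(e1$values), nrow = length(e1$values))
  Sx <- symmetrize(t(P) %*% Rx %*% P)
  e2 <- eigen(Sx, symmetric = TRUE)   # descending eigenvalues
  Gamma <- P %*% e2$vectors
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(Gamma))) {
    k <- which.max(abs(Gamma[, j]))
    if (Gamma[k, j] < 0) Gamma[, j] <- -Gamma[, j]
  }
  list(Gamma = Gamma, eigvals = pmin(pmax(e2$values, 0), 1))
}

new_filter_model <- function(Gamma, eigvals, M, method, Rx, Ry,
                             tau = NA_integer_, sigma = NA_real_,
                             channel_names = NULL, fs = NA_real_,
                             label_map = c("1", "2")) {
  structure(
    list(Gamma = Gamma, eigvals = eigvals, M = as.integer(M),
         method = method, Rx = Rx, Ry = Ry,
         tau = as.integer(tau), sigma = as.numeric(sigma),
         channel_names = channel_names, fs = as.numeric(fs),
         label_map = label_map),
    class = "spatial_filter_model"
  )
}

#' @export
print.spatial_filter_model <- function(x, ...) {
  cat("spatial_filter_model:", toupper(x$method), "with", ncol(x$Gamma),
      "channels, M =", x$M, "filter pairs\n")
  if (!is.na(x$tau))   cat("  tau   =", x$tau, "samples\n")
  if (!is.na(x$sigma)) cat("  sigma =", signif(x$sigma, 5), "\n")
  cat("  class-X eigenvalues:",
      paste(signif(x$eigvals, 3), collapse = " "), "\n")
  invisible(x)
}

check_M <- function(M, N) {
  if (!is_scalar_number(M) || M < 1 || M != round(M))
    stop_validation("M must be a positive integer")
  if (2 * M > N)
    stop_validation("2M (", 2 * M, ") exceeds the channel count N = ", N)
  as.integer(M)
}

# Optional ridge: Rx + delta I, Ry + delta I before solving (off by default;
# no silent regularization so that method comparisons stay clean).
apply_ridge <- function(R, delta) {
  if (delta > 0) R + diag(delta, nrow(R)) else R
}

# Per-trial "gram" matrix feeding the covariance average: the plain
# cross-product X X' for CSP, or the Laplacian quadratic form X L X' for
# the weighted methods.
trial_gram <- function(t, method, tau = NA, sigma = NA) {
  X <- t$data
  if (method == "csp") return(tcrossprod(X))
  kind <- switch(method,
    ltccsp = "correlation", ltcsp = "euclidean", uniform = "uniform",
    stop_validation("unknown method: ", method))
  gram_from_lag_weights(X, lag_weights(t, kind, tau, sigma = sigma))
}

# Gram for the feature path: variance is taken about the row mean, so CSP
# centers each channel first; for the weighted methods L annihilates the
# constant vector, hence rows of Gamma' X L^{1/2} are zero-mean already and
# the fitting gram doubles as the feature gram.
feature_gram <- function(t, method, tau = NA, sigma = NA) {
  if (method == "csp") {
    Xc <- t$data - rowMeans(t$data)
    return(tcrossprod(Xc))
  }
  trial_gram(t, method, tau = tau, sigma = sigma)
}

# Normalize a gram to a unit-trace covariance estimate, rejecting the
# degenerate all-zero case (e.g. tau = 1 makes L = 0).
gram_to_cov <- function(G, energy) {
  tr <- sum(diag(G))
  if (tr <= 1e-12 * max(1, energy))
    stop_degenerate("tr(X L X') ~ 0: weights carry no temporal contrast ",
                    "(tau = 1 degenerate band?)")
  G / tr
}

fit_from_grams <- function(grams, energies, labels, M, method,
                           tau = NA, sigma = NA, channel_names = NULL,
                           fs = NA, label_map = c("1", "2"), ridge = 0) {
  Rs <- mapply(gram_to_cov, grams, energies, SIMPLIFY = FALSE)
  avg <- function(cls) {
    idx <- which(labels == cls)
    Reduce(`+`, Rs[idx]) / length(idx)
  }
  Rx <- avg(1L); Ry <- avg(2L)
  sol <- solve_simultaneous_diag(apply_ridge(Rx, ridge),
                                 apply_ridge(Ry, ridge))
  new_filter_model(sol$Gamma, sol$eigvals, M, method, Rx, Ry,
                   tau = tau, sigma = sigma,
                   channel_names = channel_names, fs = fs,
                   label_map = label_map)
}

fit_generic <- function(ts, M, method, tau = NA, sigma = NA, ridge = 0) {
  stopifnot(inherits(ts, "trial_set"))
  check_both_classes(ts)
  M <- check_M(M, n_channels(ts))
  grams <- lapply(ts$trials, trial_gram, method = method,
                  tau = tau, sigma = sigma)
  energies <- vapply(ts$trials, function(t) sum(t$data^2), numeric(1))
  fit_from_grams(grams, energies, ts$labels, M, method,
                 tau = tau, sigma = sigma,
                 channel_names = ts$channel_names, fs = ts$fs,
                 label_map = ts$label_map, ridge = ridge)
}

#' Fit conventional CSP spatial filters
#'
#' Averages the plain trace-normalized covariances of each class and
#' solves the simultaneous diagonalization; the `M` columns with the
#' largest and the `M` with the smallest class-X eigenvalues are used as
#' spatial filters downstream.
#'
#' @param ts Training [trial_set()] with both classes present.
#' @param M Filter pairs per side (default 3); requires `2M <= N`.
#' @param ridge Optional ridge `delta` added to both class covariances
#'   before solving (default 0: no regularization).
#' @return A `spatial_filter_model`.
#' @export
fit_csp <- function(ts, M = 3L, ridge = 0) {
  fit_generic(ts, M, "csp", ridge = ridge)
}

#' Fit LTCSP spatial filters (Euclidean temporal weights)
#'
#' Per trial: build the banded Gaussian-kernel weight matrix
#' ([euclidean_weights()]), its Laplacian, and the weighted normalized
#' covariance; then average per class and solve as in CSP.
#'
#' @inheritParams fit_csp
#' @param tau Local temporal range in samples.
#' @param sigma Kernel scale, or `"auto"` for `7 * sigma0(ts)`.
#' @return A `spatial_filter_model` carrying `tau` and `sigma`.
#' @export
fit_ltcsp <- function(ts, M = 3L, tau, sigma = "auto", ridge = 0) {
  stopifnot(inherits(ts, "trial_set"))
  if (identical(sigma, "auto")) {
    s0 <- sigma0(ts)
    if (s0 <= 0)
      stop_degenerate("sigma0 = 0: squared sample norms have no spread, ",
                      "cannot auto-scale the Euclidean kernel")
    sigma <- 7 * s0
  }
  fit_generic(ts, M, "ltcsp", tau = tau, sigma = sigma, ridge = ridge)
}

#' Fit LTCCSP spatial filters (correlation temporal weights)
#'
#' Per trial: build the banded exp(Pearson-correlation) weight matrix
#' ([correlation_weights()]), its Laplacian, and the weighted normalized
#' covariance; then average per class and solve as in CSP. Compared with
#' LTCSP this needs only `tau`, and its weights are invariant to constant
#' offsets applied across all channels of a sample vector.
#'
#' @inheritParams fit_ltcsp
#' @return A `spatial_filter_model` carrying `tau`.
#' @export
fit_ltccsp <- function(ts, M = 3L, tau, ridge = 0) {
  if (!is_scalar_number(tau) || tau < 2)
    stop_validation("LTCCSP requires tau >= 2")
  fit_generic(ts, M, "ltccsp", tau = tau, ridge = ridge)
}

#' Serialize a spatial filter model to a JSON file
#'
#' Stores the filter matrix (row-major), eigenvalues, filter count,
#' method tag and fitted parameters; [read_filter_model()] restores the
#' model to full double precision.
#'
#' @param model A `spatial_filter_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_model <- function(model, path) {
  stopifnot(inherits(model, "spatial_filter_model"))
  obj <- list(
    method = model$method,
    M = model$M,
    n_channels = ncol(model$Gamma),
    tau = model$tau,
    sigma = model$sigma,
    fs = model$fs,
    channel_names = model$channel_names,
    label_map = as.character(model$label_map),
    eigvals = model$eigvals,
    Gamma_row_major = as.vector(t(model$Gamma)),
    Rx_row_major = as.vector(t(model$Rx)),
    Ry_row_major = as.vector(t(model$Ry))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a spatial filter model written by [write_filter_model()]
#'
#' @param path File path.
#' @return A `spatial_filter_model`.
#' @export
read_filter_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  N <- obj$n_channels
  unflatten <- function(v) matrix(as.numeric(v), N, N, byrow = TRUE)
  new_filter_model(
    Gamma = unflatten(obj$Gamma_row_major),
    eigvals = as.numeric(obj$eigvals),
    M = obj$M, method = obj$method,
    Rx = unflatten(obj$Rx_row_major), Ry = unflatten(obj$Ry_row_major),
    tau = if (is.null(obj$tau)) NA_integer_ else obj$tau,
    sigma = if (is.null(obj$sigma)) NA_real_ else obj$sigma,
    channel_names = obj$channel_names,
    fs = if (is.null(obj$fs)) NA_real_ else obj$fs,
    label_map = obj$label_map
  )
}
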