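# Online feature extraction: temporally weight a trial through L^{1/2},
# project through the selected spatial filters, take log-variances.

#' Symmetric square root of a temporal Laplacian
#'
#' Eigendecomposes the positive semidefinite Laplacian and returns
#' `V sqrt(d) V'`, with eigenvalues inside the numerical tolerance band
#' `[-1e-10 * lambda_max, 0)` clipped to 0. Satisfies
#' `L^{1/2} (L^{1/2})' = L`.
#'
#' @param L A `temporal_laplacian` (or plain symmetric PSD matrix).
#' @return An S x S symmetric PSD matrix.
#' @export
laplacian_sqrt <- function(L) {
  Lm <- if (inherits(L, "temporal_laplacian")) L$L else L
  e <- eigen(symmetrize(Lm), symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (min(e$values) < -PSD_RTOL * max(lmax, .Machine$double.eps))
    stop_validation("matrix is not positive semidefinite ",
                    "(min eigenvalue ", format(min(e$values), digits = 3),
                    "): not a Laplacian")
  d <- pmax(e$values, 0)
  symmetrize(e$vectors %*% (sqrt(d) * t(e$vectors)))
}

# Selected filter columns: first M (largest class-X eigenvalues) then
# last M (smallest).
selected_columns <- function(N, M) c(seq_len(M), seq.int(N - M + 1L, N))

#' Extract log-variance features from a trial
#'
#' Builds the trial's own temporal weight matrix with the model's method
#' and parameters, forms `Z = Gamma_sel' C L^{1/2}` (for plain CSP the
#' `L^{1/2}` step is the identity), and returns the natural log of the
#' sample variance (denominator `S - 1`, about the row mean) of each of
#' the `2M` rows of `Z`. Because `L` annihilates the constant vector,
#' each weighted row of `Z` is exactly zero-mean, so the variances are
#' computed through the quadratic form `gamma' C L C' gamma / (S - 1)`
#' without forming `L^{1/2}` explicitly.
#'
#' @param model A fitted `spatial_filter_model`.
#' @param t An [trial()] with the model's channel count.
#' @return A `feature_vector`: list with `values` (length `2M`) and
#'   `filter_ids` (column indices of `Gamma`, first `M` then last `M`).
#' @export
extract_features <- function(model, t) {
  stopifnot(inherits(model, "spatial_filter_model"),
            inherits(t, "eeg_trial"))
  N <- ncol(model$Gamma)
  if (nrow(t$data) != N)
    stop_validation("trial has ", nrow(t$data),
                    " channels; model expects ", N)
  G <- feature_gram(t, model$method, tau = model$tau, sigma = model$sigma)
  features_from_gram(model, G, ncol(t$data))
}

features_from_gram <- function(model, G, S) {
  ids <- selected_columns(ncol(model$Gamma), model$M)
  Gsel <- model$Gamma[, ids, drop = FALSE]
  v <- colSums(Gsel * (G %*% Gsel)) / (S - 1)  # diag(Gsel' G Gsel)/(S-1)
  bad <- which(v <= 0)
  if (length(bad))
    stop_degenerate("zero variance after filter ", ids[bad[1L]],
                    ": cannot take log-variance")
  structure(list(values = log(v), filter_ids = ids),
            class = "feature_vector")
}

#' Feature matrix for a whole trial set
#'
#' Applies [extract_features()] to each trial and stacks the results.
#'
#' @param model A fitted `spatial_filter_model`.
#' @param ts A [trial_set()].
#' @return Numeric matrix, trials x `2M`, with the labels attached as
#'   attribute `"labels"` and feature names `f<j>` for filter column `j`.
#' @export
feature_table <- function(model, ts) {
  stopifnot(inherits(ts, "trial_set"))
  feats <- lapply(ts$trials, function(t) extract_features(model, t)$values)
  X <- do.call(rbind, feats)
  ids <- selected_columns(ncol(model$Gamma), model$M)
  colnames(X) <- paste0("f", ids)
  attr(X, "labels") <- ts$labels
  X
}

#' Export a feature table as CSV
#'
#' Writes rows = trials with the `2M` feature columns plus a final
#' `label` column.
#'
#' @param model A fitted `spatial_filter_model`.
#' @param ts A [trial_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(model, ts, path) {
  X <- feature_table(model, ts)
  df <- as.data.frame(X)
  df$label <- attr(X, "labels")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
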