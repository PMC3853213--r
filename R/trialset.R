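#' Construct a single epoched EEG trial
#'
#' A trial is an `N x S` real matrix of channel recordings (rows = channels,
#' columns = time samples, microvolts by convention) together with its
#' sampling rate. Units are metadata only: every downstream quantity is
#' trace- or variance-normalized, so no rescaling is ever applied.
#'
#' @param data Numeric matrix, `N` channels x `S` samples, all finite,
#'   with `N >= 2` and `S >= 2`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Optional character vector of length `N`; defaults to
#'   `"ch1" ... "chN"`.
#' @return An object of class `eeg_trial`.
#' @examples
#' tr <- trial(matrix(rnorm(20), 4, 5), fs = 100)
#' dim(tr$data)
#' @export
trial <- function(data, fs, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_validation("trial data must be a numeric matrix (channels x samples)")
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop_validation("trial must have at least 2 channels and 2 samples, got ",
                    nrow(data), " x ", ncol(data))
  if (!all(is.finite(data)))
    stop_validation("trial data contains non-finite values (NaN/Inf)")
  if (!is_scalar_number(fs) || fs <= 0)
    stop_validation("fs must be a positive number")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop_validation("channel_names length (", length(channel_names),
                    ") does not match channel count (", nrow(data), ")")
  storage.mode(data) <- "double"
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_names = as.character(channel_names)),
    class = "eeg_trial"
  )
}

#' Construct a set of labelled EEG trials
#'
#' All trials must share channel count, sample count, sampling rate and
#' channel order. Labels are canonicalized to `{1, 2}` with 1 = "class X"
#' (the class whose projected variance the filters maximize); incoming
#' labels are mapped by first-seen order unless `label_map` fixes the
#' mapping explicitly.
#'
#' @param trials List of [trial()] objects.
#' @param labels Vector of per-trial class labels (two distinct values).
#' @param label_map Optional length-2 vector naming which incoming label
#'   becomes class 1 and which class 2, e.g. `c("left", "right")`.
#' @return An object of class `trial_set` with elements `trials`, `labels`
#'   (integer, in `{1, 2}`), `fs`, `channel_names`, and `label_map`.
#' @examples
#' ts <- trial_set(
#'   list(trial(matrix(rnorm(20), 4, 5), 100),
#'        trial(matrix(rnorm(20), 4, 5), 100)),
#'   labels = c("left", "right")
#' )
#' ts$labels
#' @export
trial_set <- function(trials, labels, label_map = NULL) {
  if (!is.list(trials) || length(trials) == 0L)
    stop_validation("trial_set needs a non-empty list of trials")
  if (!all(vapply(trials, inherits, logical(1), "eeg_trial")))
    stop_validation("all elements of `trials` must be eeg_trial objects")
  if (length(labels) != length(trials))
    stop_validation("labels length (", length(labels),
                    ") does not match trial count (", length(trials), ")")
  ref <- trials[[1L]]
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (nrow(tr$data) != nrow(ref$data))
      stop_validation("trial ", i, " has ", nrow(tr$data),
                      " channels; expected ", nrow(ref$data))
    if (ncol(tr$data) != ncol(ref$data))
      stop_validation("trial ", i, " has ", ncol(tr$data),
                      " samples; expected ", ncol(ref$data))
    if (!isTRUE(all.equal(tr$fs, ref$fs)))
      stop_validation("trial ", i, " has fs = ", tr$fs,
                      "; expected ", ref$fs)
    if (!identical(tr$channel_names, ref$channel_names))
      stop_validation("trial ", i, " channel order differs from trial 1")
  }
  labels <- canonicalize_labels(labels, label_map)
  structure(
    list(trials = trials, labels = labels$labels, fs = ref$fs,
         channel_names = ref$channel_names, label_map = labels$map),
    class = "trial_set"
  )
}

canonicalize_labels <- function(labels, label_map = NULL) {
  raw <- as.character(labels)
  if (is.null(label_map)) {
    if (is.numeric(labels)) {
      if (!all(labels %in% c(1, 2)))
        stop_validation("numeric label outside {1, 2}: ",
                        paste(unique(labels[!labels %in% c(1, 2)]),
                              collapse = ", "))
      map <- c("1", "2")
    } else {
      map <- unique(raw)
      if (length(map) > 2L)
        stop_validation("more than two distinct labels: ",
                        paste(map, collapse = ", "))
    }
  } else {
    map <- as.character(label_map)
    if (length(map) != 2L)
      stop_validation("label_map must name exactly two labels")
  }
  if (!all(raw %in% map))
    stop_validation("label outside the two-class set {",
                    paste(map, collapse = ", "), "}: ",
                    paste(unique(setdiff(raw, map)), collapse = ", "))
  list(labels = match(raw, map), map = map)
}

#' @export
print.trial_set <- function(x, ...) {
  n <- nrow(x$trials[[1L]]$data); s <- ncol(x$trials[[1L]]$data)
  cat("trial_set:", length(x$trials), "trials,", n, "channels x", s,
      "samples @", x$fs, "Hz\n")
  cat("  class 1 (X):", sum(x$labels == 1L), "trials;  class 2 (Y):",
      sum(x$labels == 2L), "trials\n")
  invisible(x)
}

n_channels <- function(ts) nrow(ts$trials[[1L]]$data)
n_samples  <- function(ts) ncol(ts$trials[[1L]]$data)
n_trials   <- function(ts) length(ts$trials)

# Both classes must be present before a model can be fitted.
check_both_classes <- function(ts) {
  if (sum(ts$labels == 1L) < 1L || sum(ts$labels == 2L) < 1L)
    stop_validation("both classes must be present for fitting (have ",
                    sum(ts$labels == 1L), " / ", sum(ts$labels == 2L),
                    " trials)")
  invisible(ts)
}

#' Read a trial set from a manifest of delimited-text matrices
#'
#' The manifest is a CSV with columns `trial_file`, `label`, `fs`; each
#' `trial_file` (resolved relative to the manifest location) is a plain CSV
#' of floats, rows = channels, columns = samples. Trial order follows the
#' manifest. An optional header row of channel names in the matrix files is
#' not supported: files are pure numbers.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param label_map Optional explicit two-label mapping (see [trial_set()]).
#' @return A [trial_set()].
#' @seealso [write_trialset()]
#' @export
read_trialset <- function(manifest_path, label_map = NULL) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("trial_file", "label", "fs")
  if (!all(needed %in% names(man)))
    stop_validation("manifest must have columns ",
                    paste(needed, collapse = ", "))
  if (nrow(man) == 0L)
    stop_validation("manifest lists no trials")
  base <- dirname(manifest_path)
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- man$trial_file[i]
    path <- if (file.exists(f)) f else file.path(base, f)
    if (!file.exists(path))
      stop("trial matrix file not found: ", f, " (trial ", i, ")")
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    if (!is.numeric(m) || !all(is.finite(m)))
      stop_validation("trial ", i, " (", f, ") contains non-numeric or ",
                      "non-finite values")
    trials[[i]] <- trial(m, fs = man$fs[i])
  }
  if (length(unique(man$fs)) != 1L)
    stop_validation("all trials must share the same sampling rate; manifest ",
                    "lists: ", paste(unique(man$fs), collapse = ", "))
  trial_set(trials, man$label, label_map = label_map)
}

#' Write a trial set as per-trial CSV matrices plus a manifest
#'
#' Values are written with 17 significant digits so that
#' `read_trialset(write_trialset(ts))` reproduces the data to better than
#' 1e-12 relative error.
#'
#' @param ts A [trial_set()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly usable with [read_trialset()].
#' @export
write_trialset <- function(ts, out_dir) {
  stopifnot(inherits(ts, "trial_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir)
  files <- sprintf("trial_%04d.csv", seq_along(ts$trials))
  for (i in seq_along(ts$trials)) {
    m <- format(ts$trials[[i]]$data, digits = 17, scientific = TRUE,
                trim = TRUE)
    utils::write.table(m, file.path(out_dir, files[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  # canonical {1,2} labels: numeric labels round-trip without depending on
  # first-seen order in the manifest
  man <- data.frame(
    trial_file = files,
    label = ts$labels,
    fs = ts$fs,
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
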