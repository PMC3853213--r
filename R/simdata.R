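# Synthetic two-class motor-imagery EEG with known mixing ground truth,
# impulsive-outlier contamination, and the robustness benchmark.

#' Synthetic EEG generator configuration
#'
#' The generator emulates the variance-difference structure that CSP-type
#' methods exploit: band-limited Gaussian sources whose variances differ
#' between the two classes (ERD/ERS-like lateralization) are mixed
#' linearly into channels through a seeded random orthonormal matrix, and
#' white sensor noise is added.
#'
#' Defaults describe a desk-scale two-class recording: 15 channels, 500
#' samples (2 s at 250 Hz), 50 trials per class, sources band-limited to
#' 8-30 Hz with two mirrored discriminative sources (variance 4 in the
#' favoured class vs 1 in the other) and moderate sensor noise.
#'
#' @param n_channels Channel count `N`.
#' @param n_samples Samples per trial `S`.
#' @param fs Sampling rate (Hz).
#' @param trials_per_class Trials per class `K`.
#' @param n_sources Source count (`<= N`); defaults to `N` so the mixing
#'   is invertible.
#' @param var_profiles 2 x `n_sources` matrix of per-class source
#'   variances (row 1 = class 1); `NULL` gives the default two mirrored
#'   discriminative sources at variances (4, 1) / (1, 4) with all others
#'   at 1.
#' @param source_band Band limits (Hz) of the sources.
#' @param noise_std Sensor noise standard deviation.
#' @param seed Integer seed; the whole trial set is reproducible from it.
#' @param mixing_seed Seed for the mixing matrix alone (default: `seed`).
#'   A train/test pair from the same simulated subject must share
#'   `mixing_seed` (same forward model) while differing in `seed`.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_channels = 15L, n_samples = 500L, fs = 250,
                             trials_per_class = 50L,
                             n_sources = n_channels,
                             var_profiles = NULL,
                             source_band = c(8, 30),
                             noise_std = 0.5, seed = 1L,
                             mixing_seed = seed) {
  if (n_sources > n_channels)
    stop_validation("n_sources must not exceed n_channels")
  if (noise_std < 0)
    stop_validation("noise_std must be nonnegative")
  if (is.null(var_profiles)) {
    var_profiles <- matrix(1, 2L, n_sources)
    var_profiles[1L, 1L] <- 4
    if (n_sources >= 2L) {
      var_profiles[2L, 1L] <- 1
      var_profiles[1L, 2L] <- 1
      var_profiles[2L, 2L] <- 4
    }
  }
  var_profiles <- as.matrix(var_profiles)
  if (nrow(var_profiles) != 2L || ncol(var_profiles) != n_sources)
    stop_validation("var_profiles must be a 2 x n_sources matrix")
  if (any(var_profiles < 0))
    stop_validation("source variances must be nonnegative")
  structure(
    list(n_channels = as.integer(n_channels),
         n_samples = as.integer(n_samples), fs = as.numeric(fs),
         trials_per_class = as.integer(trials_per_class),
         n_sources = as.integer(n_sources),
         var_profiles = var_profiles,
         source_band = source_band, noise_std = as.numeric(noise_std),
         seed = as.integer(seed),
         mixing_seed = as.integer(mixing_seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic two-class trial set with ground truth
#'
#' Sources are white Gaussian processes band-pass filtered to
#' `source_band` (so the signal model matches the pipeline's
#' preprocessing), rescaled to the exact per-class variances, mixed
#' through an orthonormal `N x n_sources` matrix `A`, and corrupted with
#' white sensor noise. Because `A` has orthonormal columns, the true
#' unmixing direction of source `j` is `A[, j]` itself, which is what the
#' filter-recovery tests compare against.
#'
#' @param cfg A [generator_config()].
#' @return List with `trialset` (a [trial_set()], class-1 trials first)
#'   and `ground_truth`: the `mixing` matrix, `discriminative_sources`
#'   (indices whose class variances differ), and the per-class
#'   `var_profiles`.
#' @export
generate_trials <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  N <- cfg$n_channels; S <- cfg$n_samples; K <- cfg$trials_per_class
  ns <- cfg$n_sources
  A <- with_seed(cfg$mixing_seed,
                 qr.Q(qr(matrix(stats::rnorm(N * ns), N, ns))))
  with_seed(cfg$seed, {
    bf <- signal::butter(4, cfg$source_band / (cfg$fs / 2), type = "pass")
    # generate with padding so filter transients do not touch the trial
    pad <- min(200L, S)
    make_trial <- function(cls) {
      raw <- matrix(stats::rnorm(ns * (S + 2L * pad)), ns)
      src <- t(apply(raw, 1L, function(s) signal::filtfilt(bf, s)))
      src <- src[, pad + seq_len(S), drop = FALSE]
      # impose the exact class variance on each source
      sdv <- sqrt(rowMeans((src - rowMeans(src))^2))
      tgt <- sqrt(cfg$var_profiles[cls, ])
      src <- (src - rowMeans(src)) * ifelse(sdv > 0, tgt / sdv, 0)
      X <- A %*% src
      if (cfg$noise_std > 0)
        X <- X + matrix(stats::rnorm(N * S, sd = cfg$noise_std), N, S)
      trial(X, fs = cfg$fs)
    }
    trials <- c(lapply(seq_len(K), function(i) make_trial(1L)),
                lapply(seq_len(K), function(i) make_trial(2L)))
    labels <- rep(c(1L, 2L), each = K)
    ts <- trial_set(trials, labels)
  })
  disc <- which(abs(cfg$var_profiles[1L, ] - cfg$var_profiles[2L, ]) > 0)
  list(trialset = ts,
       ground_truth = list(mixing = A,
                           discriminative_sources = disc,
                           var_profiles = cfg$var_profiles))
}

#' Outlier contamination specification
#'
#' One outlier event contaminates a single uniformly chosen (trial,
#' time-point) pair; the number of events is `round(freq * n)` with `n`
#' the trial count. The outlier amplitude is drawn from the Gaussian
#' `N(mu + 30 sigma, (30 sigma)^2)`, where `mu` and `sigma` default to
#' the pooled mean and standard deviation of all scalar samples of the
#' clean set being contaminated.
#'
#' @param freq Occurrence frequency as a fraction of the trial count
#'   (the conventional sweep is 0 to 0.4 in steps of 0.1).
#' @param mu,sigma Centre/scale statistics of the clean data; `NULL`
#'   means "compute from the trial set at injection time".
#' @param mode How one event hits the N channels of its time point:
#'   `"per_channel"` adds an independent draw to every channel,
#'   `"constant"` adds the same single draw to every channel (a constant
#'   vector, the transient-baseline-shift case), `"single_channel"` hits
#'   one random channel only.
#' @param seed Integer seed for placement and draws.
#' @return An `outlier_spec` object.
#' @export
outlier_spec <- function(freq, mu = NULL, sigma = NULL,
                         mode = c("per_channel", "constant",
                                  "single_channel"),
                         seed = 1L) {
  if (!is_scalar_number(freq) || freq < 0)
    stop_validation("freq must be a nonnegative number")
  mode <- match.arg(mode)
  structure(list(freq = freq, mu = mu, sigma = sigma, mode = mode,
                 seed = as.integer(seed)),
            class = "outlier_spec")
}

#' Inject impulsive outliers into a trial set
#'
#' Draws `round(freq * n)` events; each event selects a uniform random
#' (trial, time-point) pair, distinct across events, and adds draws from
#' `N(mu + 30 sigma, (30 sigma)^2)` to that time point's channels
#' according to the spec's `mode`. Outliers are added to (not replacing)
#' the clean signal. The input set is returned unmodified alongside the
#' contaminated copy semantics: the function is pure.
#'
#' @param ts A [trial_set()] (typically the clean training set).
#' @param spec An [outlier_spec()].
#' @return A new contaminated [trial_set()].
#' @export
inject_outliers <- function(ts, spec) {
  stopifnot(inherits(ts, "trial_set"), inherits(spec, "outlier_spec"))
  n <- n_trials(ts)
  n_events <- round(spec$freq * n)
  if (n_events == 0L) return(ts)
  pooled <- unlist(lapply(ts$trials, function(t) as.vector(t$data)),
                   use.names = FALSE)
  mu <- spec$mu %||% mean(pooled)
  sg <- spec$sigma %||% stats::sd(pooled)
  if (!is_scalar_number(sg) || sg <= 0)
    stop_validation("outlier sigma must be positive")
  N <- n_channels(ts); S <- n_samples(ts)
  if (n_events > n * S)
    stop_validation("freq = ", spec$freq, " asks for more outlier events (",
                    n_events, ") than there are (trial, time) positions (",
                    n * S, ")")
  out <- ts
  with_seed(spec$seed, {
    # distinct positions: each event hits its own (trial, time) pair, so
    # exactly round(freq * n) time points are contaminated
    cells <- sample.int(n * S, n_events)
    trial_idx <- (cells - 1L) %/% S + 1L
    time_idx <- (cells - 1L) %% S + 1L
    for (e in seq_len(n_events)) {
      i <- trial_idx[e]; s <- time_idx[e]
      d <- out$trials[[i]]$data
      add <- switch(spec$mode,
        per_channel = stats::rnorm(N, mean = mu + 30 * sg, sd = 30 * sg),
        constant = rep(stats::rnorm(1L, mean = mu + 30 * sg, sd = 30 * sg),
                       N),
        single_channel = {
          v <- numeric(N)
          v[sample.int(N, 1L)] <- stats::rnorm(1L, mean = mu + 30 * sg,
                                               sd = 30 * sg)
          v
        })
      d[, s] <- d[, s] + add
      out$trials[[i]]$data <- d
    }
  })
  out
}

#' Outlier-robustness benchmark
#'
#' For each repetition: generate independent train and test sets from the
#' generator config (fresh seeds per repetition), contaminate the
#' training set only at each outlier frequency, and evaluate every
#' requested method; the test set always stays clean. Mean accuracies are
#' reported per (method, frequency).
#'
#' @param cfg A [generator_config()]; its `seed` is combined with `seed`
#'   and the repetition index so repetitions are independent but the whole
#'   benchmark is reproducible.
#' @param methods Character vector from `{"csp", "ltcsp", "ltccsp"}`.
#' @param freqs Outlier occurrence frequencies (fractions of the training
#'   trial count).
#' @param repetitions Number of seeded repetitions.
#' @param seed Master seed of the benchmark.
#' @param eval_cfgs Optional named list of [eval_config()] overrides per
#'   method; by default each method runs with `eval_config(method = m)`.
#' @param outlier_mode Passed to [outlier_spec()].
#' @param test_trials_per_class Size of the held-out test set.
#' @return A `robustness_result`: list with `table` (mean accuracies,
#'   methods x freqs), `runs` (long data frame of every accuracy), and
#'   the configs used.
#' @export
robustness_benchmark <- function(cfg = generator_config(),
                                 methods = c("csp", "ltcsp", "ltccsp"),
                                 freqs = seq(0, 0.4, by = 0.1),
                                 repetitions = 10L, seed = 1L,
                                 eval_cfgs = NULL,
                                 outlier_mode = "per_channel",
                                 test_trials_per_class =
                                   cfg$trials_per_class) {
  stopifnot(inherits(cfg, "generator_config"))
  methods <- match.arg(methods, c("csp", "ltcsp", "ltccsp"),
                       several.ok = TRUE)
  runs <- list()
  for (rep_i in seq_len(repetitions)) {
    # each repetition is a fresh simulated subject: new mixing matrix,
    # shared between its train and test sets
    mix_seed <- derive_seed(seed, cfg$seed, rep_i, 7)
    train_cfg <- cfg
    train_cfg$seed <- derive_seed(seed, cfg$seed, rep_i, 1)
    train_cfg$mixing_seed <- mix_seed
    test_cfg <- cfg
    test_cfg$trials_per_class <- as.integer(test_trials_per_class)
    test_cfg$seed <- derive_seed(seed, cfg$seed, rep_i, 2)
    test_cfg$mixing_seed <- mix_seed
    train <- generate_trials(train_cfg)$trialset
    test <- generate_trials(test_cfg)$trialset
    # contamination statistics come from the clean training data
    pooled <- unlist(lapply(train$trials, function(t) as.vector(t$data)),
                     use.names = FALSE)
    mu <- mean(pooled); sg <- stats::sd(pooled)
    for (fq in freqs) {
      polluted <- inject_outliers(train, outlier_spec(
        freq = fq, mu = mu, sigma = sg, mode = outlier_mode,
        seed = derive_seed(seed, cfg$seed, rep_i, 3, round(fq * 1000))))
      for (m in methods) {
        ecfg <- if (!is.null(eval_cfgs[[m]])) eval_cfgs[[m]] else
          eval_config(method = m, seed = derive_seed(seed, rep_i))
        res <- evaluate(polluted, test, ecfg)
        runs[[length(runs) + 1L]] <- data.frame(
          rep = rep_i, freq = fq, method = m,
          accuracy = res$test_accuracy,
          chosen_tau = res$chosen_tau)
      }
    }
  }
  runs <- do.call(rbind, runs)
  tab <- tapply(runs$accuracy, list(runs$method, runs$freq), mean)
  tab <- tab[methods, , drop = FALSE]
  structure(list(table = tab, runs = runs, generator = cfg,
                 methods = methods, freqs = freqs,
                 repetitions = repetitions, seed = seed),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat("robustness_benchmark:", x$repetitions,
      "repetitions; mean accuracies (%):\n")
  print(round(100 * x$table, 1))
  invisible(x)
}

#' Write a robustness benchmark result to disk
#'
#' Emits the mean-accuracy table as CSV (rows = frequencies, columns =
#' methods) and a JSON run record with configs and per-repetition
#' accuracies.
#'
#' @param result A `robustness_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_benchmark <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "robustness_result"))
  if (!is.null(csv_path)) {
    tab <- t(result$table)  # rows = freqs, columns = methods
    df <- data.frame(freq = rownames(tab), tab, check.names = FALSE)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    rec <- list(
      generator = unclass(result$generator),
      methods = result$methods, freqs = result$freqs,
      repetitions = result$repetitions, seed = result$seed,
      mean_accuracy = as.data.frame.table(result$table,
                                          responseName = "accuracy"),
      runs = result$runs
    )
    jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv_path, json = json_path))
}
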