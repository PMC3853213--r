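# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; keeps the result inside 32-bit range.
derive_seed <- function(seed, ...) {
  offsets <- c(...)
  s <- (as.numeric(seed) + sum(as.numeric(offsets) * 10007)) %% 2147483629
  as.integer(s) + 1L
}

stop_validation <- function(...) {
  stop(structure(
    class = c("ltccsp_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_degenerate <- function(...) {
  stop(structure(
    class = c("ltccsp_degenerate_error", "ltccsp_validation_error",
              "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

symmetrize <- function(A) (A + t(A)) / 2
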