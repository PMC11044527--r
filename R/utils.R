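# Internal helpers shared across modules.

# Classed conditions so callers can distinguish gating/IO/parameter failures.
stop_cd26 <- function(msg, class = "cd26_error", call. = FALSE) {
  stop(structure(
    class = c(class, "cd26_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

warn_cd26 <- function(msg, class = "cd26_warning") {
  warning(structure(
    class = c(class, "cd26_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-sample seed stream derived from one master seed.
# Keeps every derived seed a valid 32-bit R integer.
split_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop_cd26(sprintf("%s must be a single integer >= %s", name, min),
              class = "cd26_parameter_error")
  }
  as.integer(x)
}
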