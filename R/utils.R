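## Internal error helpers: every user-facing failure is classed so callers
## (and the CLI) can distinguish bad configuration from bad data.

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crosslight_config_error", "crosslight_error")))
}

abort_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crosslight_data_error", "crosslight_error")))
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort_config("'%s' must be a single integer >= %d (got %s)",
                 name, min, paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort_config("'%s' must be a finite scalar in [%s, %s]", name,
                 format(lower), format(upper))
  }
  as.numeric(x)
}

## Derive a stream-specific seed from a base seed without exceeding .Machine
## integer range; keeps independent stages decoupled under one user seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
## afterwards (library code never perturbs the user's stream).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
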