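# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round to nearest integer, ties away from zero (printed-table convention).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Classed conditions so callers (and the CLI wrapper) can map errors to
# usage (exit 2) vs data (exit 1) failures.
stop_usage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("agemirnet_usage_error", "agemirnet_error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("agemirnet_data_error", "agemirnet_error")))
}

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Package-level cache (exact null distributions, calibration lookups).
.agemirnet_cache <- new.env(parent = emptyenv())
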