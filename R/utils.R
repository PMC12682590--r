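# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb user-level streams.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive reproducible sub-seeds from a master seed, one per named component,
# keeping every value inside the 32-bit integer range.
fan_out_seeds <- function(seed, components) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(components))
  })
  names(s) <- components
  s
}

stop_validation <- function(...) {
  stop(..., call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_validation(sprintf("`%s` must be in [%s, %s], got %s",
                            name, format(lower), format(upper), format(x)))
  }
  invisible(x)
}

# Euclidean lengths of the consecutive segments of an ordered point matrix.
segment_lengths <- function(points) {
  d <- diff(points)
  sqrt(rowSums(d * d))
}
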