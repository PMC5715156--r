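# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
  }
  force(code)
}

# Deterministic stream of sub-seeds derived from one master seed; keeps every
# derived seed a valid 32-bit integer.
sub_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 31 + 7919 * (as.double(k) + 1)
  as.integer(s %% 2147483647) + 1L
}

# Nearest-rank sample percentile: the ceiling(q*B)-th order statistic.
# +Inf values sort above all finite values, so upper percentiles stay defined
# even when some replicates are degenerate.
percentile_nearest_rank <- function(x, q) {
  stopifnot(all(q >= 0 & q <= 1))
  s <- sort(x)  # Inf sorts last; NA not expected
  n <- length(s)
  idx <- pmax(1L, pmin(n, as.integer(ceiling(q * n))))
  s[idx]
}

# Equal-tailed interval bounds with closest achieved tail mass: on a discrete
# resampling distribution the nearest-rank quantile systematically overshoots
# the nominal tail (it takes the first value whose CDF crosses the level, so
# the realized tail can be far from alpha/2). Matching the achieved tail
# probability to the nominal one instead gives the equal-tailed interval whose
# coverage is closest to nominal. For continuous samples the two conventions
# coincide to within one order statistic.
tail_match_bounds <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  u <- sort(unique(x))
  n <- length(x)
  below <- vapply(u, function(v) sum(x < v), numeric(1)) / n
  above <- vapply(u, function(v) sum(x > v), numeric(1)) / n
  c(u[which.min(abs(below - a))], u[which.min(abs(above - a))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}
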