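# Internal helpers shared across the pipeline.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL leaves the
# global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sampling rate of a ts object (samples per second in this package's
# convention: time unit is the second).
ts_fs <- function(x) {
  stopifnot(stats::is.ts(x))
  stats::tsp(x)[3L]
}

ts_times <- function(x) as.numeric(stats::time(x))

ts_start <- function(x) stats::tsp(x)[1L]

ts_duration <- function(x) length(x) / ts_fs(x)

# Robust amplitude scale: 95th percentile of |x - median(x)|.
amp_scale <- function(v) {
  s <- stats::quantile(abs(v - stats::median(v)), 0.95, names = FALSE)
  if (!is.finite(s) || s <= 0) s <- max(abs(v), 1e-12)
  s
}

stop_invalid <- function(...) stop(..., call. = FALSE)
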