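# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. A NULL seed runs under the ambient RNG stream.
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

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("avbind_invalid_argument", "error")))
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be positive")
  invisible(x)
}

# Linear-interpolation resampling of a sampled sequence onto a new rate;
# constant extrapolation at the edges.
resample_linear <- function(x, from_rate, to_rate, n_out) {
  t_out <- (seq_len(n_out) - 1) / to_rate
  t_in <- (seq_along(x) - 1) / from_rate
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

# Derive a stream of child seeds from a master seed, kept within 32-bit range.
derive_seeds <- function(seed, n, salt = 0L) {
  with_seed(seed + salt, sample.int(.Machine$integer.max, n))
}
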