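# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive per-unit sub-seeds from a master seed (documented counter scheme:
# the master seed fixes the RNG, and n sub-seeds are drawn in one block).
derive_subseeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Centered moving average with edge truncation; width in samples (>= 1).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = FALSE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "pulsefusion_config_error")
  }
  ok_lo <- if (allow_equal_lower) x >= lower else x > lower
  ok_hi <- if (allow_equal_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x),
          class = "pulsefusion_config_error")
  }
  invisible(x)
}
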