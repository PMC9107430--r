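# Internal helpers: error classes, seed handling, small numeric utilities.

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "fcreact_config_error", ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "fcreact_data_error", ...)
}

abort_numeric <- function(msg, ...) {
  rlang::abort(msg, class = "fcreact_numeric_error", ...)
}

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort_config(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = TRUE, open_hi = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort_config(sprintf(
      "`%s` must be a single number in %s%g, %g%s", name,
      if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]"
    ))
  }
  as.numeric(x)
}

# Run code under a local RNG state so callers' streams are untouched and a
# given seed always reproduces the same draws.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-iteration seed stream from one master seed.  Seeds are
# drawn once with `sample.int` so the derivation is stable across platforms
# and documented: seeds_from(master, n)[i] is iteration i's seed.
seeds_from <- function(master_seed, n) {
  with_seed_(master_seed, sample.int(.Machine$integer.max, n))
}

# Moment-matched Beta parameters; used for change-rate distributions.
beta_moments <- function(mean, sd) {
  v <- sd^2
  if (v <= 0 || v >= mean * (1 - mean)) {
    abort_config(sprintf(
      "cannot moment-match a Beta distribution to mean %.3f, sd %.3f (need 0 < sd^2 < mean*(1-mean))",
      mean, sd
    ))
  }
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}
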