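# Internal argument checking helpers. All validation errors name the offending
# field so callers can correct synthetic-data or fit specifications directly.

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be >= 0 (got %g).", name, x))
  }
  invisible(x)
}

.check_numeric <- function(x, name, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x)) {
    abort(sprintf("`%s` must be a non-empty numeric vector without NA.", name))
  }
  if (nonneg && any(x < 0)) {
    abort(sprintf("`%s` must be >= 0 everywhere (min = %g).", name, min(x)))
  }
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Runs `expr` under a fixed RNG seed when given, leaving the caller's RNG
# state untouched; generators are bit-reproducible under a fixed seed.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  .check_count(seed, "seed", min = 0L)
  withr::with_seed(as.integer(seed), expr)
}

.require_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must contain column%s %s.",
      what, if (length(missing) > 1) "s" else "",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(data)
}
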