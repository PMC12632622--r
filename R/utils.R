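# Internal helpers shared across modules.

# Derive a child seed from a user seed and a stage label, so that each
# stochastic stage of a pipeline is independently reproducible from one
# explicit seed. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, key, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(seed) + 7919 * h + 104729 * counter) %% 2147483647)
}

set_stage_seed <- function(seed, key, counter = 0L) {
  if (!is.null(seed)) set.seed(derive_seed(seed, key, counter))
  invisible(NULL)
}

# Round to the nearest multiple of 0.5; exact halves (x.25, x.75) round
# away from zero.
round_to_half <- function(x) {
  sign(x) * floor(2 * abs(x) + 0.5) / 2
}

# Timepoint labels "T0", "T1", ... used in wide table headers.
tp_label <- function(t) paste0("T", t)

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s",
                  name, x,
                  if (strict_lower) "(" else "[", lower, upper,
                  if (strict_upper) ")" else "]"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
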