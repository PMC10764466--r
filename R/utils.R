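## Internal helpers: seed discipline and input validation.
##
## All stochastic entry points take an explicit `seed` argument and evaluate
## their random draws inside `with_seed()`, which saves and restores the
## caller's RNG state so no function mutates global randomness.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

## Deterministic stream of child seeds, kept below 2^31 so they remain valid
## R integers. Used to give every segment/fold/run its own independent seed.
derive_seed <- function(seed, i) {
  as.integer((abs(seed) %% 2147483629 * 69069 + i * 7919) %% 2147483629) + 1L
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

assert_probability <- function(x, name) assert_scalar_number(x, name, 0, 1)

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

## Unique per-recording segment key used to join tables.
segment_key <- function(participant_id, segment_index) {
  paste(participant_id, segment_index, sep = ":")
}

## argmax with ties resolved to the lowest chaos level (conservative).
argmax_lowest <- function(p) which(p == max(p))[1] - 1L
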