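# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (x > 0 || (allow_zero && x == 0)) &&
    (x < 1 || (allow_one && x == 1))
  if (!ok) stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min &&
    x == as.integer(x)
  if (!ok) stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable row ordering without locale-dependent string sorting
order_stable <- function(...) order(..., method = "radix")
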