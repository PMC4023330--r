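# internal helpers shared across modules

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible substream seed from a master seed and a stream name.
# Every stochastic operation draws from its own named substream so that adding
# draws to one stage never perturbs another. Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.integer(seed)) %% 80000L) * 26041L + (h %% 100000L))
}

#' @keywords internal
#' @noRd
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

#' @keywords internal
#' @noRd
assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("`%s` must be > %g (got %g)", name, min, x), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("`%s` must be >= %g (got %g)", name, min, x), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
#' @noRd
assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
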