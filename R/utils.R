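# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded generators do not disturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

# sample moments beyond mean/sd (used by descriptives and tests)
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

sample_kurtosis <- function(x) {
  # excess kurtosis
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
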