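# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded generators do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# log(sum(exp(x))) without overflow; x a numeric vector
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp with per-column additive log-weights lw
row_logsumexp <- function(mat, lw) {
  mat <- sweep(mat, 2L, lw, `+`)
  m <- apply(mat, 1L, max)
  m + log(rowSums(exp(mat - m)))
}

# "+-+" <-> c(1L, -1L, 1L)
steps_to_string <- function(steps) {
  paste(ifelse(steps > 0, "+", "-"), collapse = "")
}

string_to_steps <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  ifelse(ch == "+", 1L, -1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
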