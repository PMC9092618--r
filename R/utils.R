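# Internal helpers shared across modules.

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so that seeded package functions never
#' disturb the caller's random-number stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic fan-out so that pipeline stages are independently
#' reproducible. Result is always a valid 32-bit integer seed.
#' @param seed master integer seed
#' @param stage stage label (character) or index
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (is.character(stage)) stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + stage * 10007) %% 2147483562L) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# n-denominator (population) moments used by Lin's CCC
mom_var <- function(x) mean((x - mean(x))^2)
mom_cov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))
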