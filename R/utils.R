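# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a local RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded package functions never clobber the global
#' random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# stop() with a condition class so callers/tests can distinguish error kinds
abort2 <- function(msg, class) {
  stop(structure(
    class = c(class, "normtraj_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# largest-remainder apportionment of n into counts proportional to weights
largest_remainder <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  quota <- n * w
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    # ties broken by position so the allocation is deterministic
    ord <- order(quota - base, seq_along(w), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
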