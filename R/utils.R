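# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not disturb the
#' caller's RNG stream. A `NULL` seed evaluates the code unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# two-sided normal p-value from an estimate and its standard error
pval_normal <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

# two-sided t p-value
pval_t <- function(beta, se, df) {
  2 * stats::pt(-abs(beta / se), df = df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
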