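# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All user-facing failures carry a condition class so callers (and the
#' pipeline) can branch on the failure kind rather than matching messages.
#'
#' @param message error message
#' @param class condition subclass, e.g. "mrsuite_config_error"
#' @noRd
mr_abort <- function(message, class) {
  stop(structure(
    class = c(class, "mrsuite_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_config <- function(message) mr_abort(message, "mrsuite_config_error")
abort_empty <- function(message) mr_abort(message, "mrsuite_empty_input_error")
abort_insufficient <- function(message) mr_abort(message, "mrsuite_insufficient_instruments_error")

# two-sided normal p-value for z = est/se
pval_z <- function(est, se) 2 * stats::pnorm(-abs(est / se))

# normal-theory CI bounds
ci_normal <- function(est, se, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  c(est - z * se, est + z * se)
}

# local RNG scope: run `expr` under `seed` without disturbing the caller's
# RNG stream; seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a stream of child seeds from one master seed (kept < 2^31)
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
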