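#' Evaluate an expression under a temporary RNG seed
#'
#' All randomness in the package flows through this helper: the caller's
#' `.Random.seed` is saved, the expression is run under `set.seed(seed)`,
#' and the global RNG state is restored afterwards, so every generator and
#' trainer is a pure function of its arguments.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Stable digest of an R object
#'
#' Used for model checkpoints and run-manifest config digests.
#'
#' @param x any R object.
#' @return a character hash.
#' @export
object_digest <- function(x) {
  rlang::hash(x)
}

#' Round half up to a given number of digits
#'
#' Display rounding for percentages: 0.5 always rounds away from zero,
#' matching how agreement percentages are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits digits to keep (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: stop unless condition, with sprintf-style message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
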