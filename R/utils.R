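# Internal helpers shared across modules.

#' Signal a classed coexmod error
#'
#' @param msg message
#' @param class condition subclass (prefixed with "coexmod_")
#' @param ... extra condition fields
#' @noRd
stop_coexmod <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "coexmod_error", "error")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so package functions never
#' clobber the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_coexmod("`seed` must be a single integer", "coexmod_bad_seed")
  }
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

#' Derive a child seed from a root seed and a stream tag
#'
#' Deterministic, stays below 2^31 so it is a valid R integer seed.
#' @noRd
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

#' @noRd
is_square_symmetric <- function(x, tol = 1e-8) {
  is.matrix(x) && nrow(x) == ncol(x) &&
    max(abs(x - t(x))) <= tol
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Mean of off-diagonal entries of a square matrix
#' @noRd
mean_offdiag <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(NA_real_)
  (sum(x) - sum(diag(x))) / (n * (n - 1L))
}
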