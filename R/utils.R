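#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generators behave as pure functions of their truth
#' objects without disturbing the session's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Derive a deterministic sub-stream seed
#'
#' Maps a (global seed, stream index) pair to a reproducible child seed below
#' 2^31, so per-replicate noise streams are independent of each other and of
#' replicate ordering.
#'
#' @param seed integer global seed.
#' @param i stream index (>= 1).
#' @return integer seed.
#' @keywords internal
substream_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(i))
  as.integer((abs(as.double(seed)) * 48271 + as.double(i) * 100003) %% 2147483587)
}

# stop() with a consistent condition class so callers can catch validation
# failures distinctly from numerical failures
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("holophos_validation_error", "error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
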