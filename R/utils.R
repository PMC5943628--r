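#' @keywords internal
stop_relex <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "relex_error"), call = call))
}

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
#' state afterwards.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stream of child seeds from a master seed.
#'
#' Keeps derived seeds inside the 32-bit integer range so they remain valid
#' arguments to [set.seed()].
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
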