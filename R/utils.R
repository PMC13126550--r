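# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed without disturbing the global stream
#'
#' @param seed integer seed or NULL (code runs on the current stream).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a base seed; keeps values inside 32-bit range
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 7919) %% 2147483647)
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_cfg(...)
  invisible(TRUE)
}
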