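# Physical constants shared across modules.
# Gas constant in kJ mol^-1 K^-1 and kcal mol^-1 K^-1.
.R_KJ <- 8.314462618e-3
.R_KCAL <- 1.987204259e-3

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded at `seed`, then
#' restores the caller's RNG state, so that generators are reproducible
#' without clobbering the session stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  invisible(x)
}
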