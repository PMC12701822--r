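#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois dnorm sd t.test pt cor quantile approx median
#'   runif var coef residuals
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, evaluates `expr`, and restores the caller's RNG
#' state, so stochastic package functions never disturb the session stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## derive a child seed from a base seed and a stream label, staying < 2^31
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562) + 1L
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("dsbchrom_data_error", "error")))
}

## index (1-based) of the bin containing 0-based position `pos`
pos_to_bin <- function(pos, bin_size, origin = 0) {
  as.integer(floor((pos - origin) / bin_size)) + 1L
}

fmt_bp <- function(x) {
  if (abs(x) >= 1e6 && x %% 1e5 == 0) paste0(x / 1e6, " Mb")
  else if (abs(x) >= 1e3 && x %% 100 == 0) paste0(x / 1e3, " kb")
  else paste0(x, " bp")
}
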