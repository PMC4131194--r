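# shared internal helpers

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. With `seed = NULL`
#' the code runs against the ambient RNG stream.
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# clamped linear interpolation of a drift trajectory over [0, 1]
lerp <- function(from, to, t) from + (to - from) * pmin(pmax(t, 0), 1)

# format doubles for on-disk series: 9 significant digits round-trips exactly
# through read/format at the declared precision
fmt_series <- function(x) sprintf("%.9g", x)
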