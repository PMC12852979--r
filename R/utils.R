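#' @importFrom methods new validObject slot is slotNames
#' @importFrom stats kmeans lm coef fitted resid sd median rnorm runif
#'   setNames complete.cases optimize pt quantile
#' @importFrom utils read.csv write.csv head tail
NULL

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Wrap an angle in degrees to the interval (-90, 90].
wrapHalf <- function(deg) {
  out <- ((deg + 90) %% 180) - 90
  out[out == -90] <- 90
  out
}

rmseOf <- function(obs, pred) sqrt(mean((obs - pred)^2))

## Message used for unit conversions so they are never silent.
logConversion <- function(what, from, to, factor) {
  message(sprintf("converting %s from %s to %s (x %g)", what, from, to, factor))
}

stopIfNot <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
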