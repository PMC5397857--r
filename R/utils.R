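#' Wrap phases to (-pi, pi]
#'
#' @param x numeric vector/matrix of phases in radians.
#' @return phases wrapped into the half-open interval (-pi, pi].
#' @examples
#' wrapPhase(c(pi, -pi, 3 * pi / 2))
#' @export
wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Circular mean of angles
#'
#' Argument of the (optionally weighted) mean unit phasor.
#'
#' @param x angles in radians.
#' @param w optional nonnegative weights.
#' @return scalar angle in (-pi, pi]; `NaN` when the mean phasor is 0.
#' @export
circularMean <- function(x, w = NULL) {
  z <- if (is.null(w)) mean(exp(1i * x)) else
    sum(w * exp(1i * x)) / sum(w)
  if (Mod(z) < .Machine$double.eps) return(NaN)
  Arg(z)
}

# unwrap a phase series (vector) so successive differences are in (-pi, pi]
unwrapPhase <- function(x) {
  if (length(x) < 2) return(x)
  x[1] + c(0, cumsum(wrapPhase(diff(x))))
}

# run code under a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a stream of distinct 31-bit sub-seeds from one master seed
splitSeed <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
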