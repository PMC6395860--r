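# Small shared helpers: angle arithmetic and seeded evaluation.

#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians.
#' @return angles wrapped to the principal interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# circular distance |a - b| on the circle, in [0, pi]
circ_dist <- function(a, b) abs(wrap_angle(a - b))

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# z-score a vector; constant vectors map to zeros rather than NaN
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
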