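#' Step-function evaluation
#'
#' Right-continuous step evaluation of a curve given by knots
#' \code{times} and \code{values}: the value at a query is the value at the
#' largest knot at or before it; queries before the first knot return the
#' first value.
#'
#' @param times increasing knot times.
#' @param values vector (or matrix, one row per knot) of values.
#' @param at query times.
#' @return Vector or matrix of values at \code{at}.
#' @export
eval_step <- function(times, values, at) {
  ix <- findInterval(at, times)
  ix[ix < 1L] <- 1L
  if (is.matrix(values)) values[ix, , drop = FALSE] else values[ix]
}

#' Mean residual squared error between two step curves
#'
#' The squared L2 distance \eqn{\|f-g\|^2 = \int_s^\tau (f(t)-g(t))^2 dt}
#' between two scalar step functions, computed as a left-endpoint Riemann
#' sum over the union of their jump times (exact for step functions).
#'
#' @param f,g two-column objects (time, value) — matrices, data frames, or
#'   lists with elements \code{times} and \code{values}.
#' @param window integration window \code{c(s, tau)}.
#' @return Nonnegative scalar.
#' @examples
#' f <- cbind(time = c(0, 1, 2), value = c(0, 1, 0))
#' mrse(f, cbind(0, 0), window = c(0, 3))  # = 1
#' @export
mrse <- function(f, g, window) {
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  f <- as_step(f); g <- as_step(g)
  u <- sort(unique(c(window[1L], f$times, g$times)))
  u <- u[u >= window[1L] & u < window[2L]]
  width <- diff(c(u, window[2L]))
  d <- eval_step(f$times, f$values, u) - eval_step(g$times, g$values, u)
  sum(width * d^2)
}

as_step <- function(f) {
  if (is.list(f) && !is.data.frame(f)) {
    stopifnot(!is.null(f$times), !is.null(f$values))
    return(f[c("times", "values")])
  }
  f <- as.matrix(f)
  list(times = f[, 1L], values = f[, 2L])
}

#' Pointwise empirical bias and variance of replicate curves
#'
#' @param replicates matrix of replicate curve values, one row per
#'   repetition, one column per grid time.
#' @param truth vector of true values on the same grid.
#' @return List with \code{bias} (mean of replicates minus truth) and
#'   \code{variance} (pointwise sample variance), each a vector over the
#'   grid.
#' @export
pointwise_bias_variance <- function(replicates, truth) {
  replicates <- as.matrix(replicates)
  stopifnot(nrow(replicates) >= 2L, length(truth) == ncol(replicates))
  list(bias = colMeans(replicates) - truth,
       variance = apply(replicates, 2L, stats::var))
}

#' Pointwise empirical coverage of interval bounds
#'
#' Proportion of repetitions whose interval contains the truth, at each
#' grid time.
#'
#' @param lower,upper matrices of interval bounds (repetition x grid time).
#' @param truth vector of true values on the grid.
#' @return Vector of coverage proportions in \eqn{[0, 1]}.
#' @export
coverage_curve <- function(lower, upper, truth) {
  lower <- as.matrix(lower); upper <- as.matrix(upper)
  stopifnot(identical(dim(lower), dim(upper)),
            length(truth) == ncol(lower))
  colMeans(sweep(lower, 2L, truth, `<=`) & sweep(upper, 2L, truth, `>=`))
}
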