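#' Greenwood-type plug-in variance for product-integral curves
#'
#' Pointwise variance estimates for each component of the transition
#' probability curve \eqn{e_l \prod (I + \Delta\hat\Lambda(u))} by the
#' standard plug-in covariance recursion for Aalen-Johansen estimators: the
#' running covariance of the probability row is sandwiched with each factor
#' \eqn{F(u) = I + \Delta\hat\Lambda(u)} and incremented by the plug-in
#' multinomial covariance of the increment row of every origin state,
#' weighted by the squared current occupancy:
#' \deqn{V(u) = F(u)^\top V(u-) F(u) + \sum_j p_j(u-)^2\, C_j(u),}
#' with \eqn{C_j} built from terms
#' \eqn{\Delta\bar N_{jk}(\bar Y_j - \Delta\bar N_{jk}) / \bar Y_j^3} and
#' \eqn{-\Delta\bar N_{jk}\Delta\bar N_{jk'} / \bar Y_j^3}.  The recursion
#' assumes independent increments, i.e. the Markov property; for landmark
#' and hybrid curves it can underestimate the variance, and the
#' nonparametric bootstrap ([bootstrap_transprob()]) is the recommended
#' alternative.  For a hybrid hazard the covariance between increments
#' estimated from different samples (landmark vs full) is set to zero.
#'
#' @param haz a \code{"cumhaz"} (full-sample, landmark or hybrid).
#' @param l landmark state (single state).
#' @param t right end of the evaluation window.
#' @return List with \code{times} and \code{var}: a matrix of pointwise
#'   variance estimates of \eqn{\hat P_{lk}(s, \cdot)}, one column per state.
#' @examples
#' haz <- nelson_aalen(aggregate_processes(toy_histories(), c(0, 5)))
#' greenwood_variance(haz, l = 1)
#' @export
greenwood_variance <- function(haz, l, t = haz$tau) {
  stopifnot(inherits(haz, "cumhaz"), length(l) == 1L)
  init <- numeric(haz$space$K)
  init[l] <- 1
  keep <- haz$times <= t
  sub <- haz
  sub$times <- haz$times[keep]
  sub$delta <- haz$delta[keep, , , drop = FALSE]
  sub$risk <- haz$risk[keep, , , drop = FALSE]
  sub$events <- haz$events[keep, , , drop = FALSE]
  list(times = c(haz$origin, sub$times),
       var = greenwood_recursion(sub, init))
}

## covariance recursion; returns (T+1) x K matrix of diagonal entries
greenwood_recursion <- function(haz, init) {
  K <- haz$space$K
  nt <- length(haz$times)
  out <- matrix(0, nt + 1L, K)
  p <- as.numeric(init)
  V <- matrix(0, K, K)
  I <- diag(K)
  for (m in seq_len(nt)) {
    D <- haz$delta[m, , ]
    Fm <- I + D
    add <- matrix(0, K, K)
    for (j in seq_len(K)) {
      if (p[j] == 0) next
      y <- haz$risk[m, j, ]
      n <- haz$events[m, j, ]
      if (all(n == 0L)) next
      S <- matrix(0, K, K)            # cov of the off-diagonal increments
      for (k in seq_len(K)) {
        if (k == j || y[k] == 0L) next
        S[k, k] <- n[k] * (y[k] - n[k]) / y[k]^3
        for (k2 in seq_len(K)) {
          if (k2 == j || k2 == k || y[k2] == 0L) next
          if (y[k2] == y[k])          # same estimation sample: multinomial
            S[k, k2] <- -n[k] * n[k2] / y[k]^3
        }
      }
      Cj <- S
      Cj[j, ] <- -colSums(S)
      Cj[, j] <- -rowSums(S)
      Cj[j, j] <- sum(S)
      add <- add + p[j]^2 * Cj
    }
    V <- crossprod(Fm, V %*% Fm) + add
    p <- as.numeric(p %*% Fm)
    out[m + 1L, ] <- diag(V)
  }
  out
}
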