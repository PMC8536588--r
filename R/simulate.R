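#' Frailty models for the simulation engine
#'
#' Subject-level random multipliers \eqn{V_{jk}} on the baseline transition
#' rates \eqn{\alpha_{jk}}.  Conditional on its frailty vector each subject
#' follows a time-homogeneous Markov chain with intensities
#' \eqn{\lambda_{jk} = V_{jk}\alpha_{jk}}; marginally over a non-degenerate
#' frailty the process is non-Markov.
#'
#' \code{frailty_none()} fixes all multipliers at 1 (Markov).
#' \code{frailty_gamma()} puts a gamma multiplier with mean 1 and variance
#' \code{variance} on a single transition (default 2 -> 1) and 1 elsewhere;
#' the gamma is moment-matched with shape = rate = 1/variance, and
#' \code{variance = 0} degenerates to 1.  \code{frailty_lognormal()} draws
#' the whole vector \eqn{V} jointly log-normal with mean 1 and covariance
#' matrix \code{Sigma} (on the transition order of the state space), via
#' \eqn{W = \log V} normal with \eqn{E W_j = -\log(1+\Sigma_{jj})/2} and
#' \eqn{\mathrm{cov}(W_j, W_k) = \log(1+\Sigma_{jk})}, which reproduces the
#' requested mean and covariance exactly.
#'
#' When \eqn{\log(1+\Sigma)} is not a valid covariance matrix (which happens
#' for the bundled default \code{Sigma}, a published matrix rounded to two
#' decimals), \code{repair = TRUE} projects the correlation matrix of
#' \eqn{W} to the nearest correlation matrix ([Matrix::nearPD()]) while
#' keeping \eqn{\mathrm{var}(W_j) = \log(1+\Sigma_{jj})} fixed, so the mean
#' (1) and the variances (\eqn{\Sigma_{jj}}) of \eqn{V} are preserved and
#' only the infeasible correlations move.  With \code{repair = FALSE} such a
#' matrix is rejected, reporting the offending eigenvalue.
#'
#' @param variance frailty variance \eqn{\sigma^2 \ge 0}.
#' @param transition the transition carrying the gamma frailty.
#' @param Sigma 4x4 (generally |E| x |E|) target covariance matrix of V.
#' @param repair repair a non-positive-definite \eqn{\log(1+\Sigma)} as
#'   described above.
#' @return An object of class \code{"frailty_model"}.
#' @export
frailty_none <- function() {
  structure(list(kind = "none"), class = "frailty_model")
}

#' @rdname frailty_none
#' @export
frailty_gamma <- function(variance, transition = c(2L, 1L)) {
  stopifnot(variance >= 0)
  structure(list(kind = "gamma_single", variance = variance,
                 transition = as.integer(transition)),
            class = "frailty_model")
}

#' @rdname frailty_none
#' @export
frailty_lognormal <- function(Sigma = lognormal_frailty_sigma(),
                              repair = TRUE) {
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == ncol(Sigma), isSymmetric(unname(Sigma)))
  structure(list(kind = "lognormal_joint", Sigma = Sigma, repair = repair),
            class = "frailty_model")
}

#' @export
print.frailty_model <- function(x, ...) {
  switch(x$kind,
    none = cat("No frailty (all multipliers 1)\n"),
    gamma_single = cat("Gamma frailty on transition ",
                       x$transition[1L], "->", x$transition[2L],
                       ": mean 1, variance ", x$variance, "\n", sep = ""),
    lognormal_joint = {
      cat("Joint log-normal frailty, mean 1, covariance:\n")
      print(x$Sigma)
    })
  invisible(x)
}

#' Default covariance matrix for the joint log-normal frailty
#'
#' The bundled 4x4 covariance of \eqn{(V_{12}, V_{13}, V_{21}, V_{23})} with
#' strong positive and negative cross-transition correlations, used by the
#' second simulation experiment.
#'
#' @return 4x4 numeric matrix.
#' @export
lognormal_frailty_sigma <- function() {
  matrix(c(0.80,  0.57, -0.35,  0.37,
           0.57,  0.42, -0.12,  0.19,
          -0.35, -0.12,  0.96, -0.63,
           0.37,  0.19, -0.63,  0.45), 4L, 4L)
}

## W-scale covariance, repaired if requested; errors otherwise when infeasible
lognormal_w_cov <- function(Sigma, repair) {
  CW <- log(1 + Sigma)
  ev <- eigen(CW, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    if (!repair)
      stop("log(1 + Sigma) is not positive semi-definite ",
           "(smallest eigenvalue ", format(min(ev)), "); ",
           "set repair = TRUE to project to the nearest valid correlation")
    sdw <- sqrt(diag(CW))
    R <- CW / tcrossprod(sdw)
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    CW <- R * tcrossprod(sdw)
  }
  CW
}

#' Draw frailty vectors
#'
#' @param model a [frailty_none()] / [frailty_gamma()] /
#'   [frailty_lognormal()] object.
#' @param n number of subjects.
#' @param transitions two-column matrix fixing the column order (default:
#'   the illness-death-with-recovery transitions).
#' @param seed optional integer; sets the RNG seed locally.
#' @return n x (number of transitions) matrix of positive multipliers, one
#'   column per transition.
#' @examples
#' colMeans(draw_frailties(frailty_gamma(2), 1000, seed = 1))
#' @export
draw_frailties <- function(model, n,
                           transitions = illness_death_recovery()$transitions,
                           seed = NULL) {
  stopifnot(inherits(model, "frailty_model"), n >= 1L)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  nT <- nrow(transitions)
  cn <- paste(transitions[, 1L], transitions[, 2L], sep = "-")
  V <- matrix(1, n, nT, dimnames = list(NULL, cn))
  if (model$kind == "gamma_single" && model$variance > 0) {
    col <- match(paste(model$transition, collapse = "-"), cn)
    if (is.na(col)) stop("frailty transition not in the transition set")
    shape <- 1 / model$variance
    V[, col] <- stats::rgamma(n, shape = shape, rate = shape)
  } else if (model$kind == "lognormal_joint") {
    if (nrow(model$Sigma) != nT)
      stop("Sigma dimension does not match the number of transitions")
    CW <- lognormal_w_cov(model$Sigma, model$repair)
    e <- eigen(CW, symmetric = TRUE)
    rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    W <- matrix(stats::rnorm(n * nT), n, nT) %*% rt
    V[, ] <- exp(sweep(W, 2L, diag(CW) / 2, `-`))
  }
  V
}

#' Simulate multi-state event histories
#'
#' Simulates \code{n} independent subjects on \code{[0, tau]}.  Conditional
#' on its frailty vector each subject is a time-homogeneous Markov chain
#' with off-diagonal intensities \eqn{V_{jk}\,\alpha_{jk}}, generated by
#' competing exponential sojourns: the sojourn time in state j is
#' exponential with the total exit rate and the destination is drawn
#' proportionally to the individual rates.  A subject still in a transient
#' state at \code{tau} gets a final row with \code{to = 0} at \code{tau};
#' a subject entering an absorbing state ends with that transition row.
#'
#' @param n number of subjects.
#' @param rates baseline rates, one per transition of \code{space} (default:
#'   the illness-death-with-recovery rates \code{c(0.12, 0.03, 0.15, 0.1)}).
#' @param tau administrative end of observation.
#' @param frailty a \code{"frailty_model"}.
#' @param space a [state_space()].
#' @param initial initial state: a single state, or a length-K probability
#'   vector to draw each subject's initial state from.
#' @param seed optional integer; sets the RNG seed locally, making the
#'   output a deterministic function of \code{(n, seed)}.
#' @return An [event_history()].
#' @examples
#' h <- simulate_histories(100, frailty = frailty_gamma(2), seed = 7)
#' @export
simulate_histories <- function(n, rates = c(0.12, 0.03, 0.15, 0.1),
                               tau = 1000, frailty = frailty_none(),
                               space = illness_death_recovery(),
                               initial = 1L, seed = NULL) {
  stopifnot(n >= 1L, tau > 0, length(rates) == nrow(space$transitions),
            all(rates >= 0))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  K <- space$K
  V <- draw_frailties(frailty, n, transitions = space$transitions)
  if (length(initial) == 1L) {
    start <- rep(as.integer(initial), n)
  } else {
    stopifnot(length(initial) == K, all(initial >= 0), sum(initial) > 0)
    start <- sample.int(K, n, replace = TRUE, prob = initial)
  }
  ## per-state list of outgoing transition rows
  out_rows <- lapply(seq_len(K), function(j) which(space$transitions[, 1L] == j))
  acc <- vector("list", n)
  for (i in seq_len(n)) {
    lam_i <- V[i, ] * rates
    t0 <- 0
    state <- start[i]
    rows <- list()
    repeat {
      cand <- out_rows[[state]]
      tot <- sum(lam_i[cand])
      if (tot <= 0) {               # rate-free state: censor at tau
        rows[[length(rows) + 1L]] <- c(t0, tau, state, 0L)
        break
      }
      t1 <- t0 + stats::rexp(1L, tot)
      if (t1 > tau) {
        rows[[length(rows) + 1L]] <- c(t0, tau, state, 0L)
        break
      }
      dest_row <- if (length(cand) == 1L) cand
                  else cand[sample.int(length(cand), 1L,
                                       prob = lam_i[cand])]
      dest <- space$transitions[dest_row, 2L]
      rows[[length(rows) + 1L]] <- c(t0, t1, state, dest)
      if (!length(out_rows[[dest]]) || t1 >= tau) break  # absorbed or at tau
      t0 <- t1
      state <- dest
    }
    m <- length(rows)
    acc[[i]] <- cbind(id = rep(i, m), do.call(rbind, rows))
  }
  df <- as.data.frame(do.call(rbind, acc))
  names(df) <- c("id", "entry", "exit", "from", "to")
  event_history(df, space)
}

#' Simulation-based oracle for the true transition probabilities
#'
#' Under a frailty model the marginal process is non-Markov and the true
#' transition probability \eqn{P_l(s, t)} has no convenient closed form, so
#' it is approximated by the mean over \code{reps} independent simulated
#' cohorts of the landmark Aalen-Johansen estimator, each cohort of size
#' \code{n}, averaged pointwise on a fixed evaluation grid.
#'
#' @param s,l landmark time and state.
#' @param reps number of simulation repetitions.
#' @param n cohort size per repetition.
#' @param grid evaluation times; default 200 equally spaced points on
#'   \code{(s, tau]}.
#' @inheritParams simulate_histories
#' @return List with \code{times} (the grid) and \code{probs} (grid x K
#'   matrix of averaged probability rows).
#' @export
true_probability_oracle <- function(s, l, reps, n = 1000L,
                                    rates = c(0.12, 0.03, 0.15, 0.1),
                                    tau = 1000, frailty = frailty_none(),
                                    space = illness_death_recovery(),
                                    initial = 1L, seed = NULL,
                                    grid = NULL) {
  stopifnot(reps >= 1L)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(grid)) grid <- seq(s, tau, length.out = 201L)[-1L]
  tot <- matrix(0, length(grid), space$K)
  for (r in seq_len(reps)) {
    h <- simulate_histories(n, rates, tau, frailty, space, initial)
    fit <- transprob(h, s, l, tau, method = "lmaj")
    tot <- tot + predict(fit, grid)
  }
  list(times = grid, probs = tot / reps)
}
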