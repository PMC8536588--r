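#' Product integral of a cumulative hazard
#'
#' Time-ordered finite product \eqn{\prod_{u \le t} (I + \Delta\hat\Lambda(u))}
#' applied to an initial row vector.  Each factor has nonnegative entries and
#' rows summing to one, so every value of the curve is a probability vector.
#'
#' @param haz a \code{"cumhaz"}.
#' @param init initial probability row vector (length K), e.g. the unit
#'   vector of the landmark state.
#' @param t right end of the evaluation window; defaults to the hazard's.
#' @return List with \code{times} (origin time followed by the jump times up
#'   to \code{t}) and \code{probs} (matrix, one probability row per time).
#' @export
product_integral <- function(haz, init, t = haz$tau) {
  stopifnot(inherits(haz, "cumhaz"), t >= haz$origin,
            length(init) == haz$space$K)
  keep <- which(haz$times <= t)
  nt <- length(keep)
  K <- haz$space$K
  probs <- matrix(0, nt + 1L, K)
  p <- as.numeric(init)
  probs[1L, ] <- p
  for (m in seq_len(nt)) {
    p <- p + p %*% haz$delta[keep[m], , ]
    probs[m + 1L, ] <- p
  }
  list(times = c(haz$origin, haz$times[keep]), probs = probs)
}

#' Transition probabilities in a (partially non-Markov) multi-state model
#'
#' Fits one of three product-integral estimators of the transition
#' probability vector \eqn{P_l(s, t) = (P_{l1}(s,t), ..., P_{lK}(s,t))} on
#' the window \code{(s, tau]}:
#' \describe{
#'   \item{\code{"aj"}}{the Aalen-Johansen estimator, using full-sample
#'     Nelson-Aalen rates (consistent under the Markov assumption);}
#'   \item{\code{"lmaj"}}{the landmark Aalen-Johansen estimator, using only
#'     the subsample in state(s) \code{l} at time \code{s} (consistent
#'     without the Markov assumption, at the price of a smaller risk set);}
#'   \item{\code{"haj"}}{the hybrid landmark Aalen-Johansen estimator, which
#'     takes landmark rates for the transitions in the non-Markov set
#'     \code{nonmarkov} and full-sample rates for all others.  With an empty
#'     set it reduces to \code{"aj"}, with the full transition set to
#'     \code{"lmaj"}.}
#' }
#'
#' @param x an [event_history()].
#' @param s landmark time.
#' @param l landmark state (or set of states; with a set, the initial vector
#'   is the empirical distribution over \code{l} at \code{s} in the sample
#'   the rates are estimated from).
#' @param tau end of the estimation window, \code{s < tau}.
#' @param method one of \code{"aj"}, \code{"lmaj"}, \code{"haj"}.
#' @param nonmarkov for \code{method = "haj"}: the non-Markov transition set
#'   (two-column matrix or \code{"j-k"} strings), typically from
#'   [select_nonmarkov()].
#' @param variance \code{"greenwood"} adds the Greenwood-type plug-in
#'   pointwise variance of each \eqn{P_{lk}(s, \cdot)} (see
#'   [greenwood_variance()]); valid under the Markov assumption and possibly
#'   anti-conservative otherwise, hence [bootstrap_transprob()] is
#'   recommended for the landmark estimators.
#' @return An object of class \code{"transprob"}: list with \code{times}
#'   (starting at \code{s}), \code{probs} (rows are probability vectors),
#'   optionally \code{var}, plus the fit metadata.  An empty landmark
#'   population yields a curve constant at the initial vector.
#' @examples
#' h <- toy_histories()
#' fit <- transprob(h, s = 0.5, l = 1, tau = 5, method = "haj",
#'                  nonmarkov = "2-1")
#' predict(fit, 4)
#' @export
transprob <- function(x, s, l, tau, method = c("aj", "lmaj", "haj"),
                      nonmarkov = NULL,
                      variance = c("none", "greenwood")) {
  method <- match.arg(method)
  variance <- match.arg(variance)
  stopifnot(inherits(x, "event_history"), s < tau)
  space <- attr(x, "state_space")
  l <- as.integer(l)
  stopifnot(all(l >= 1L), all(l <= space$K))
  haz <- switch(method,
    aj = nelson_aalen(aggregate_processes(x, c(s, tau))),
    lmaj = landmark_nelson_aalen(x, s, l, tau),
    haj = {
      A <- as_transition_set(nonmarkov, space)
      hybrid_hazard(nelson_aalen(aggregate_processes(x, c(s, tau))),
                    landmark_nelson_aalen(x, s, l, tau), A)
    })
  init_sample <- if (method == "aj") x else landmark_subset(x, s, l)
  init <- initial_vector(init_sample, s, l, space)
  pi_ <- product_integral(haz, init)
  out <- list(times = pi_$times, probs = pi_$probs, s = s, l = l, tau = tau,
              method = method, init = init,
              nonmarkov = if (method == "haj") haz$nonmarkov,
              hazard = haz, space = space, call = match.call())
  if (variance == "greenwood")
    out$var <- greenwood_recursion(haz, init)
  class(out) <- "transprob"
  out
}

## Alternative construction of the hybrid hazard: apply the plain
## Nelson-Aalen formula after removing subjects outside the landmark state
## at s from the risk sets (and event counts) of the non-Markov transitions
## only.  Must agree bitwise with hybrid_hazard(); kept as an internal
## cross-check of the estimator's two equivalent definitions.
haj_hazard_by_removal <- function(x, s, l, tau, A) {
  space <- attr(x, "state_space")
  A <- as_transition_set(A, space)
  st <- state_at(x, s)
  lm_ids <- names(st)[!is.na(st) & st %in% l]
  ev <- x$to != 0L & x$exit > s & x$exit <= tau
  times <- sort(unique(x$exit[ev]))
  K <- space$K
  delta <- array(0, c(length(times), K, K))
  seg <- occupancy_segments(x)
  seg_lm <- as.character(seg$id) %in% lm_ids
  row_lm <- as.character(x$id) %in% lm_ids
  for (r in seq_len(nrow(space$transitions))) {
    j <- space$transitions[r, 1L]; k <- space$transitions[r, 2L]
    use_lm <- !is.na(match_transition(j, k, list(transitions = A)))
    for (m in seq_along(times)) {
      u <- times[m]
      atrisk <- seg$state == j & seg$start < u & u <= seg$end
      if (use_lm) atrisk <- atrisk & seg_lm
      Y <- sum(atrisk)
      hit <- ev & x$from == j & x$to == k & x$exit == u
      if (use_lm) hit <- hit & row_lm
      n <- sum(hit)
      if (Y > 0L) delta[m, j, k] <- n / Y
    }
  }
  for (j in seq_len(K))
    delta[, j, j] <- -rowSums(delta[, j, -j, drop = FALSE])
  structure(list(times = times, delta = delta, origin = s, tau = tau,
                 space = space, nonmarkov = A),
            class = "cumhaz")
}

## e_l for a single landmark state; for a set, the empirical occupancy
## distribution over l at s in the given sample (uniform fallback when the
## sample is empty, so downstream curves stay defined)
initial_vector <- function(x, s, l, space) {
  init <- numeric(space$K)
  if (length(l) == 1L) {
    init[l] <- 1
  } else {
    st <- state_at(x, s)
    cnt <- tabulate(st[!is.na(st) & st %in% l], nbins = space$K)
    if (sum(cnt) > 0) init <- cnt / sum(cnt) else init[l] <- 1 / length(l)
  }
  init
}

#' State occupation probabilities
#'
#' The Aalen-Johansen plug-in estimator of the unconditional occupation
#' probabilities \eqn{\hat\pi(t) = \hat\pi(0)\,\hat P^{AJ}(0, t)}, where
#' \eqn{\hat\pi(0)} is the empirical occupancy distribution just after time
#' zero.  Consistent even when the process is non-Markov; with no censoring
#' it reproduces the empirical occupation fractions exactly.
#'
#' @param x an [event_history()].
#' @param t end of the evaluation window.
#' @return A \code{"transprob"} whose rows estimate \eqn{\hat\pi(\cdot)} on
#'   \code{[0, t]}.
#' @examples
#' occupation_probabilities(toy_histories(), 4)
#' @export
occupation_probabilities <- function(x, t) {
  stopifnot(inherits(x, "event_history"), t >= 0)
  space <- attr(x, "state_space")
  st <- state_at(x, 0)
  cnt <- tabulate(st[!is.na(st)], nbins = space$K)
  if (sum(cnt) == 0L) stop("no subjects under observation at time 0")
  init <- cnt / sum(cnt)
  haz <- nelson_aalen(aggregate_processes(x, c(0, max(t, x$exit))))
  pi_ <- product_integral(haz, init, t = t)
  structure(list(times = pi_$times, probs = pi_$probs, s = 0, l = NULL,
                 tau = t, method = "occupation", init = init, hazard = haz,
                 space = space, call = match.call()),
            class = "transprob")
}

#' @export
print.transprob <- function(x, digits = 4L, ...) {
  lab <- switch(x$method, aj = "Aalen-Johansen (AJ)",
                lmaj = "landmark Aalen-Johansen (LMAJ)",
                haj = "hybrid landmark Aalen-Johansen (HAJ)",
                occupation = "state occupation (AJ plug-in)")
  cat(lab, "estimator\n")
  if (x$method != "occupation")
    cat("Landmark: s =", x$s, ", l = {", paste(x$l, collapse = ","),
        "}, window (", x$s, ",", x$tau, "]\n")
  if (!is.null(x$nonmarkov) && nrow(x$nonmarkov))
    cat("Non-Markov set:", paste(x$nonmarkov[, 1L], x$nonmarkov[, 2L],
                                 sep = "->", collapse = ", "), "\n")
  last <- nrow(x$probs)
  cat("P at t =", format(x$times[last]), ":",
      paste(format(round(x$probs[last, ], digits)), collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.transprob <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- unique(stats::quantile(object$times, c(.25, .5, .75, 1),
                                    names = FALSE, type = 1L))
  p <- predict(object, times)
  out <- data.frame(time = times, p)
  names(out) <- c("time", paste0("p", seq_len(object$space$K)))
  structure(list(fit = object, table = out), class = "summary.transprob")
}

#' @export
print.summary.transprob <- function(x, ...) {
  print(x$fit)
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Evaluate a fitted transition-probability curve
#'
#' Step-function evaluation (right-continuous): the value at a query time is
#' the value at the largest jump time at or before it; queries before the
#' landmark time return the initial vector.  Values are clipped to
#' \eqn{[0, 1]} for reporting.
#'
#' @param object a \code{"transprob"}.
#' @param times numeric vector of evaluation times.
#' @param ... unused.
#' @return Matrix with one probability row per query time.
#' @export
predict.transprob <- function(object, times, ...) {
  ix <- findInterval(times, object$times)
  ix[ix < 1L] <- 1L
  out <- object$probs[ix, , drop = FALSE]
  out <- pmin(pmax(out, 0), 1)
  rownames(out) <- format(times)
  colnames(out) <- paste0("p", seq_len(ncol(out)))
  out
}

#' @export
plot.transprob <- function(x, states = seq_len(x$space$K),
                           col = seq_along(states), lty = 1, ...) {
  graphics::matplot(x$times, x$probs[, states, drop = FALSE], type = "s",
                    col = col, lty = lty, xlab = "time", ylab = "probability",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", legend = paste("state", states),
                   col = col, lty = lty, bty = "n")
  invisible(x)
}

#' Pointwise confidence intervals
#'
#' Normal-approximation intervals from the Greenwood-type plug-in variance
#' (the fit must have been made with \code{variance = "greenwood"}).
#'
#' @param object a \code{"transprob"} with a variance component.
#' @param parm unused.
#' @param level confidence level.
#' @param ... unused.
#' @return List with \code{times}, \code{lower} and \code{upper} matrices
#'   (clipped to \eqn{[0,1]}).
#' @export
confint.transprob <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$var))
    stop("fit the curve with variance = \"greenwood\" first")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(object$var, 0))
  list(times = object$times,
       lower = pmax(object$probs - z * se, 0),
       upper = pmin(object$probs + z * se, 1))
}
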