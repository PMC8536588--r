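#' Nelson-Aalen estimators of cumulative transition rates
#'
#' \code{nelson_aalen} turns aggregated processes into the matrix-valued
#' Nelson-Aalen increment process: at each jump time u the off-diagonal
#' (j, k) increment is \eqn{\Delta\bar N_{jk}(u) / \bar Y_j(u)} whenever
#' \eqn{\bar Y_j(u) > 0} (and 0 otherwise), and each diagonal entry is minus
#' the row sum of the off-diagonals.  \code{landmark_nelson_aalen} applies
#' the same estimator to the landmark subsample of subjects in states
#' \code{l} at time \code{s}, over the window \code{(s, tau]}.
#'
#' @param counts an [aggregate_processes()] result.
#' @return An object of class \code{"cumhaz"}: list with \code{times},
#'   \code{delta} (T x K x K increment array, rows summing to zero),
#'   \code{origin} (window start) and \code{space}.
#' @examples
#' nelson_aalen(aggregate_processes(toy_histories(), c(0, 5)))
#' @export
nelson_aalen <- function(counts) {
  stopifnot(inherits(counts, "msm_counts"))
  K <- counts$space$K
  nt <- length(counts$times)
  delta <- array(0, c(nt, K, K))
  risk <- array(0L, c(nt, K, K))
  if (nt) {
    for (j in seq_len(K)) {
      yj <- counts$n_risk[, j]
      pos <- yj > 0L
      for (k in seq_len(K)) if (k != j) {
        risk[, j, k] <- yj
        if (any(pos))
          delta[pos, j, k] <- counts$n_event[pos, j, k] / yj[pos]
      }
      delta[, j, j] <- -rowSums(delta[, j, -j, drop = FALSE])
    }
  }
  structure(list(times = counts$times, delta = delta,
                 risk = risk, events = counts$n_event,
                 origin = counts$window[1L], tau = counts$window[2L],
                 space = counts$space),
            class = "cumhaz")
}

#' @param x an [event_history()].
#' @param s landmark time.
#' @param l integer vector of landmark states.
#' @param tau end of the estimation window.
#' @rdname nelson_aalen
#' @export
landmark_nelson_aalen <- function(x, s, l, tau) {
  stopifnot(s < tau)
  haz <- nelson_aalen(aggregate_processes(landmark_subset(x, s, l), c(s, tau)))
  haz$landmark <- list(s = s, l = as.integer(l))
  haz
}

#' Hybrid cumulative hazard
#'
#' Merges a full-sample and a landmark Nelson-Aalen estimator transition by
#' transition: increments for transitions in the non-Markov set \code{A} are
#' taken from the landmark estimator, all others from the full-sample
#' estimator; diagonals are recomputed as negative row sums.  With
#' \code{A} empty the result equals \code{full}; with \code{A} the whole
#' transition set it equals \code{lm}.
#'
#' @param full,lm \code{"cumhaz"} objects over the same window.
#' @param A non-Markov transition set: two-column (from, to) matrix or
#'   character vector like \code{"2-1"}; must be a subset of the permitted
#'   transitions.
#' @return A \code{"cumhaz"} over the union of the two jump-time sets.
#' @export
hybrid_hazard <- function(full, lm, A) {
  stopifnot(inherits(full, "cumhaz"), inherits(lm, "cumhaz"))
  if (!isTRUE(all.equal(c(full$origin, full$tau), c(lm$origin, lm$tau))))
    stop("'full' and 'lm' must be estimated over the same window")
  space <- full$space
  A <- as_transition_set(A, space)
  in_A <- !is.na(match_transition(space$transitions[, 1L],
                                  space$transitions[, 2L],
                                  list(transitions = A)))
  times <- sort(unique(c(full$times, lm$times)))
  K <- space$K
  nt <- length(times)
  delta <- array(0, c(nt, K, K))
  risk <- array(0L, c(nt, K, K))
  events <- array(0L, c(nt, K, K))
  pick <- function(src, rows) {
    ix <- match(src$times, times)
    for (r in rows) {
      j <- space$transitions[r, 1L]; k <- space$transitions[r, 2L]
      delta[ix, j, k] <<- src$delta[, j, k]
      risk[ix, j, k] <<- src$risk[, j, k]
      events[ix, j, k] <<- src$events[, j, k]
    }
  }
  pick(full, which(!in_A))
  pick(lm, which(in_A))
  for (j in seq_len(K))
    delta[, j, j] <- -rowSums(delta[, j, -j, drop = FALSE])
  structure(list(times = times, delta = delta, risk = risk, events = events,
                 origin = full$origin, tau = full$tau, space = space,
                 landmark = lm$landmark, nonmarkov = A),
            class = "cumhaz")
}

#' Cumulative hazard value
#'
#' Cumulated K x K hazard matrix at time \code{t} (sum of increments with
#' jump time at or before \code{t}).
#'
#' @param haz a \code{"cumhaz"}.
#' @param t evaluation time.
#' @return K x K matrix.
#' @export
cumhaz_value <- function(haz, t) {
  stopifnot(inherits(haz, "cumhaz"))
  K <- haz$space$K
  keep <- haz$times <= t
  if (!any(keep)) return(matrix(0, K, K))
  apply(haz$delta[keep, , , drop = FALSE], c(2L, 3L), sum)
}

#' @export
print.cumhaz <- function(x, ...) {
  cat("Nelson-Aalen cumulative hazard on (", x$origin, ", ", x$tau, "]: ",
      length(x$times), " jump times\n", sep = "")
  if (!is.null(x$landmark))
    cat("Landmark: s =", x$landmark$s, ", l = {",
        paste(x$landmark$l, collapse = ","), "}\n")
  if (!is.null(x$nonmarkov))
    cat("Hybrid with non-Markov set:",
        paste(x$nonmarkov[, 1L], x$nonmarkov[, 2L], sep = "->",
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cumhaz <- function(x, ...) {
  tr <- x$space$transitions
  nt <- length(x$times)
  old <- graphics::par(mfrow = grDevices::n2mfrow(nrow(tr)))
  on.exit(graphics::par(old))
  for (r in seq_len(nrow(tr))) {
    j <- tr[r, 1L]; k <- tr[r, 2L]
    y <- if (nt) cumsum(x$delta[, j, k]) else numeric()
    plot(c(x$origin, x$times), c(0, y), type = "s",
         xlab = "time", ylab = bquote(Lambda[.(paste0(j, k))]), ...)
  }
  invisible(x)
}
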