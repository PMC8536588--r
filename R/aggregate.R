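#' Aggregate counting and at-risk processes
#'
#' Collapses a collection of event histories into the jump times on a window
#' \code{(s, tau]}, the aggregated at-risk counts \eqn{\bar Y_j(u)} (number of
#' subjects in state j just before u, i.e. left limits) and the transition
#' count increments \eqn{\Delta\bar N_{jk}(u)}.
#'
#' @param x an [event_history()].
#' @param window numeric length-2 vector \code{c(s, tau)}; events with time in
#'   \code{(s, tau]} are counted.
#' @return A list of class \code{"msm_counts"} with elements \code{times}
#'   (strictly increasing jump times), \code{n_risk} (length(times) x K),
#'   \code{n_event} (length(times) x K x K array), \code{window} and
#'   \code{space}.  An empty window yields zero-length times.
#' @examples
#' aggregate_processes(toy_histories(), c(0, 5))
#' @export
aggregate_processes <- function(x, window) {
  stopifnot(inherits(x, "event_history"), length(window) == 2L,
            window[1L] < window[2L])
  space <- attr(x, "state_space")
  K <- space$K
  s <- window[1L]; tau <- window[2L]
  ev <- x$to != 0L & x$exit > s & x$exit <= tau
  times <- sort(unique(x$exit[ev]))
  nt <- length(times)
  n_risk <- matrix(0L, nt, K)
  n_event <- array(0L, c(nt, K, K))
  if (nt) {
    seg <- occupancy_segments(x)
    for (j in seq_len(K)) {
      sj <- seg$state == j
      n_risk[, j] <- findInterval(times, sort(seg$start[sj]), left.open = TRUE) -
        findInterval(times, sort(seg$end[sj]), left.open = TRUE)
    }
    evr <- which(ev)
    ti <- match(x$exit[evr], times)
    idx <- ti + nt * (x$from[evr] - 1L) + nt * K * (x$to[evr] - 1L)
    n_event <- array(tabulate(idx, nbins = nt * K * K), c(nt, K, K))
  }
  structure(list(times = times, n_risk = n_risk, n_event = n_event,
                 window = c(s, tau), space = space),
            class = "msm_counts")
}

#' @export
print.msm_counts <- function(x, ...) {
  cat("Aggregated multi-state processes on (", x$window[1L], ", ",
      x$window[2L], "]: ", length(x$times), " jump times, ",
      sum(x$n_event), " transitions\n", sep = "")
  invisible(x)
}
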