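#' Nonparametric bootstrap for transition-probability curves
#'
#' Resamples subjects with replacement (each resampled subject keeps its
#' full history and gets a fresh id), recomputes the chosen estimator on
#' every replicate, and summarises the replicate curves pointwise on a
#' common evaluation grid (the union of all replicate jump times, step
#' evaluation): sample variance and percentile interval bounds.
#'
#' For the hybrid estimator the non-Markov set is by default the one fixed
#' from the original sample (\code{retest = FALSE}); with
#' \code{retest = TRUE} the grid-test selection is rerun inside every
#' replicate, propagating the selection uncertainty into the intervals
#' (\code{test_args} supplies \code{grid}, and optionally \code{B},
#' \code{alpha}, \code{variance}, to [select_nonmarkov()]).
#'
#' Replicates whose landmark population is empty are kept as curves
#' constant at the initial vector and counted in \code{n_empty_landmark}.
#'
#' @inheritParams transprob
#' @param B number of bootstrap replicates (at least 2).
#' @param level nominal level of the percentile intervals.
#' @param retest rerun the non-Markov selection per replicate.
#' @param test_args list of arguments for the per-replicate selection.
#' @param seed optional integer; sets the RNG seed locally.
#' @return Object of class \code{"transprob_boot"}: \code{times},
#'   \code{estimate} (original-sample curve on the grid), \code{var},
#'   \code{lower}, \code{upper} (matrices, one column per state),
#'   \code{replicates} (B x time x K array), \code{n_empty_landmark},
#'   \code{B}, \code{level}.
#' @examples
#' bt <- bootstrap_transprob(toy_histories(), s = 0, l = 1, tau = 5,
#'                           method = "aj", B = 50, seed = 1)
#' @export
bootstrap_transprob <- function(x, s, l, tau,
                                method = c("aj", "lmaj", "haj"),
                                nonmarkov = NULL, B = 1000L,
                                level = 0.95, retest = FALSE,
                                test_args = list(), seed = NULL) {
  method <- match.arg(method)
  stopifnot(B >= 2L, level > 0, level < 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  space <- attr(x, "state_space")
  ids <- unique(x$id)
  by_id <- split(seq_len(nrow(x)), match(x$id, ids))
  fits <- vector("list", B)
  n_empty <- 0L
  for (b in seq_len(B)) {
    pick <- sample.int(length(ids), replace = TRUE)
    rows <- unlist(by_id[pick], use.names = FALSE)
    xb <- as.data.frame(x)[rows, , drop = FALSE]
    xb$id <- rep(seq_along(pick), lengths(by_id)[pick])
    xb <- event_history(xb, space)
    A <- nonmarkov
    if (method == "haj" && retest) {
      sel <- do.call(select_nonmarkov,
                     c(list(x = xb, tau = tau), test_args))
      A <- sel$nonmarkov
    }
    if (method != "aj" && nrow(landmark_subset(xb, s, l)) == 0L)
      n_empty <- n_empty + 1L
    fits[[b]] <- transprob(xb, s, l, tau, method = method, nonmarkov = A)
  }
  grid <- sort(unique(c(s, unlist(lapply(fits, `[[`, "times")))))
  K <- space$K
  reps <- array(0, c(B, length(grid), K))
  for (b in seq_len(B)) reps[b, , ] <- predict(fits[[b]], grid)
  v <- apply(reps, c(2L, 3L), stats::var)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  lo <- apply(reps, c(2L, 3L), stats::quantile, probs = qs[1L])
  hi <- apply(reps, c(2L, 3L), stats::quantile, probs = qs[2L])
  orig <- transprob(x, s, l, tau, method = method, nonmarkov = nonmarkov)
  structure(list(times = grid, estimate = predict(orig, grid), var = v,
                 lower = lo, upper = hi, replicates = reps,
                 n_empty_landmark = n_empty, B = B, level = level,
                 method = method, s = s, l = l, tau = tau),
            class = "transprob_boot")
}

#' @export
print.transprob_boot <- function(x, ...) {
  cat("Nonparametric bootstrap (", x$B, " replicates) for the ",
      toupper(x$method), " estimator, s = ", x$s, ", l = {",
      paste(x$l, collapse = ","), "}\n", sep = "")
  cat("Pointwise variance and ", 100 * x$level,
      "% percentile intervals on ", length(x$times),
      " grid times\n", sep = "")
  if (x$n_empty_landmark > 0L)
    cat("Replicates with empty landmark population:",
        x$n_empty_landmark, "\n")
  invisible(x)
}

#' @export
plot.transprob_boot <- function(x, state = 1L, ...) {
  graphics::plot(x$times, x$estimate[, state], type = "s", ylim = c(0, 1),
                 xlab = "time", ylab = paste0("P(state ", state, ")"), ...)
  graphics::lines(x$times, x$lower[, state], type = "s", lty = 2)
  graphics::lines(x$times, x$upper[, state], type = "s", lty = 2)
  invisible(x)
}
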