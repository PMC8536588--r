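#' Frailty simulation experiments
#'
#' Monte-Carlo harness for the two frailty experiments on the
#' illness-death-with-recovery model.  Each repetition simulates a cohort,
#' selects the non-Markov transition set with the grid test applied to all
#' transitions (first group = the origin state of the tested transition,
#' second group = the remaining states), and computes the AJ, LMAJ and HAJ
#' transition-probability curves from each requested landmark time,
#' evaluated on a fixed grid.
#'
#' Experiment 1 puts a gamma frailty (mean 1, variance \code{sigma2}) on
#' the 2 -> 1 transition only; experiment 2 draws the whole frailty vector
#' jointly log-normal with covariance \code{Sigma}.  The landmark grids of
#' the two experiments differ (see [experiment_defaults()]).
#'
#' @param experiment 1 or 2.
#' @param reps number of Monte-Carlo repetitions.
#' @param n cohort size per repetition.
#' @param sigma2 gamma frailty variance (experiment 1).
#' @param Sigma frailty covariance matrix (experiment 2).
#' @param landmark_times landmark times at which curves are computed
#'   (default: the experiment's full landmark grid).
#' @param l landmark state for the reported curves.
#' @param test_grid landmark grid for the Markov grid tests (default: the
#'   experiment's landmark grid).
#' @param eval_grid fixed evaluation times for the curves; default 200
#'   equally spaced points on \code{(min(landmark_times), tau]}.
#' @param B wild-bootstrap replicates per grid test.
#' @param alpha significance level used to build the non-Markov set.
#' @param tau end of observation.
#' @param seed optional integer; sets the RNG seed locally.
#' @return List of class \code{"frailty_experiment"}: \code{curves}, a list
#'   (one element per landmark time) of \code{reps x grid x K x 3} arrays
#'   with estimator slices \code{"aj"}, \code{"lmaj"}, \code{"haj"};
#'   \code{eval_grid}; \code{nonmarkov} (per-rep selected sets);
#'   \code{selected_21} (proportion of reps selecting each transition);
#'   \code{n_empty_landmark}.
#' @export
run_frailty_experiment <- function(experiment = 1L, reps, n = 1000L,
                                   sigma2 = 0,
                                   Sigma = lognormal_frailty_sigma(),
                                   landmark_times = NULL, l = 2L,
                                   test_grid = NULL, eval_grid = NULL,
                                   B = 500L, alpha = 0.05, tau = 1000,
                                   seed = NULL) {
  stopifnot(experiment %in% c(1L, 2L), reps >= 1L)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  def <- experiment_defaults(experiment)
  if (is.null(landmark_times)) landmark_times <- def$landmark_grid
  if (is.null(test_grid)) test_grid <- def$landmark_grid
  if (is.null(eval_grid))
    eval_grid <- seq(min(landmark_times), tau, length.out = 201L)[-1L]
  frailty <- if (experiment == 1L) frailty_gamma(sigma2)
             else frailty_lognormal(Sigma)
  space <- illness_death_recovery()
  K <- space$K
  est <- c("aj", "lmaj", "haj")
  curves <- lapply(landmark_times, function(s)
    array(NA_real_, c(reps, length(eval_grid), K, 3L),
          dimnames = list(NULL, NULL, NULL, est)))
  names(curves) <- as.character(landmark_times)
  Asets <- vector("list", reps)
  sel_count <- stats::setNames(numeric(nrow(space$transitions)),
                               paste(space$transitions[, 1L],
                                     space$transitions[, 2L], sep = "-"))
  n_empty <- 0L
  for (r in seq_len(reps)) {
    h <- simulate_histories(n, def$rates, tau, frailty, space)
    sel <- select_nonmarkov(h, grid = test_grid, tau = tau, B = B,
                            alpha = alpha)
    A <- sel$nonmarkov
    Asets[[r]] <- A
    if (nrow(A))
      sel_count[paste(A[, 1L], A[, 2L], sep = "-")] <-
        sel_count[paste(A[, 1L], A[, 2L], sep = "-")] + 1
    for (si in seq_along(landmark_times)) {
      s <- landmark_times[si]
      if (nrow(landmark_subset(h, s, l)) == 0L) n_empty <- n_empty + 1L
      for (e in est) {
        fit <- transprob(h, s, l, tau, method = e,
                         nonmarkov = if (e == "haj") A)
        curves[[si]][r, , , e] <- predict(fit, eval_grid)
      }
    }
  }
  structure(list(curves = curves, eval_grid = eval_grid,
                 landmark_times = landmark_times, l = l,
                 nonmarkov = Asets, selection_rate = sel_count / reps,
                 n_empty_landmark = n_empty, experiment = experiment,
                 reps = reps, n = n, alpha = alpha, B = B),
            class = "frailty_experiment")
}

#' @export
print.frailty_experiment <- function(x, ...) {
  cat("Frailty experiment", x$experiment, "-", x$reps, "repetitions of",
      x$n, "subjects\n")
  cat("Landmark times:", paste(x$landmark_times, collapse = ", "),
      " (state", x$l, ")\n")
  cat("Grid-test selection rate per transition:\n")
  print(round(x$selection_rate, 3))
  invisible(x)
}

#' Experiment design constants
#'
#' Baseline rates, end of follow-up and the landmark grids of the two
#' frailty experiments.
#'
#' @param experiment 1 or 2.
#' @return List with \code{rates} (for transitions 1->2, 1->3, 2->1, 2->3),
#'   \code{tau} and \code{landmark_grid}.
#' @export
experiment_defaults <- function(experiment = 1L) {
  list(rates = c(0.12, 0.03, 0.15, 0.1), tau = 1000,
       landmark_grid = if (experiment == 1L)
         c(6, 9, 12, 14, 17, 20, 22, 25, 28, 30)
       else
         c(1, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24, 26, 28, 30))
}
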