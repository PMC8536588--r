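#' Two-sample log-rank statistic for one transition at one landmark time
#'
#' Building block of the Markov-property tests: subjects are grouped by the
#' state occupied at the landmark time \code{s} (\code{l1} vs \code{l2},
#' disjoint), and the occurrence of the j -> k transition over
#' \code{(s, tau]} is compared between groups with the standard two-sample
#' log-rank statistic on the transition-specific risk sets
#' \deqn{U = \sum_u \left[\Delta\bar N^{(1)}_{jk}(u) -
#'   \bar Y^{(1)}_j(u)\,\Delta\bar N_{jk}(u)/\bar Y_j(u)\right],}
#' with hypergeometric (default) or Poisson-type variance \eqn{V}; the
#' statistic is \eqn{\mathfrak{X}_s = U^2/V}, defined as 0 when \eqn{V = 0}.
#' Under the Markov property the two groups share the same j -> k intensity,
#' so large values are evidence of non-Markov behaviour of that transition.
#'
#' @param x an [event_history()].
#' @param s landmark time.
#' @param transition length-2 integer vector \code{c(j, k)} or string
#'   \code{"j-k"}.
#' @param l1,l2 disjoint sets of landmark states defining the two groups;
#'   \code{l2} defaults to all other states.
#' @param tau end of the comparison window.
#' @param variance \code{"hypergeometric"} or \code{"poisson"}.
#' @param detail return per-subject score contributions (used by the wild
#'   bootstrap) alongside the statistic.
#' @return The statistic (numeric), or with \code{detail = TRUE} a list with
#'   \code{statistic}, \code{score} (U), \code{variance} (V),
#'   \code{contributions} (named per-subject vector, zero for subjects
#'   outside both groups) and \code{empty_group} flag.
#' @details The construction compares conditional intensities given the
#'   landmark state, the landmark two-sample device used in the multi-state
#'   literature to probe Markov behaviour transition by transition.
#' @export
logrank_point_statistic <- function(x, s, transition, l1, l2 = NULL,
                                    tau, variance = c("hypergeometric",
                                                      "poisson"),
                                    detail = FALSE) {
  variance <- match.arg(variance)
  space <- attr(x, "state_space")
  transition <- as_transition_set(transition, space)
  stopifnot(nrow(transition) == 1L, s < tau)
  j <- transition[1L, 1L]; k <- transition[1L, 2L]
  l1 <- as.integer(l1)
  if (is.null(l2)) l2 <- setdiff(seq_len(space$K), l1)
  l2 <- as.integer(l2)
  if (length(intersect(l1, l2)))
    stop("'l1' and 'l2' must be disjoint")

  ids <- unique(x$id)
  st <- state_at(x, s)
  grp <- rep(NA_integer_, length(ids))
  grp[st %in% l1] <- 1L
  grp[st %in% l2] <- 2L
  empty_group <- !any(grp == 1L, na.rm = TRUE) || !any(grp == 2L, na.rm = TRUE)

  contrib <- stats::setNames(numeric(length(ids)), as.character(ids))
  zero <- list(statistic = 0, score = 0, variance = 0,
               contributions = contrib, empty_group = empty_group)
  pooled_ids <- ids[!is.na(grp)]
  if (empty_group || !length(pooled_ids))
    return(if (detail) zero else 0)

  pool <- x[x$id %in% pooled_ids, , drop = FALSE]
  ## j -> k event times in (s, tau] within the pooled sample
  ev <- pool$from == j & pool$to == k & pool$exit > s & pool$exit <= tau
  if (!any(ev)) return(if (detail) zero else 0)
  u <- sort(unique(pool$exit[ev]))

  seg <- occupancy_segments(pool)
  seg <- seg[seg$state == j, , drop = FALSE]
  seg$grp <- grp[match(seg$id, ids)]
  at_risk <- function(sg) {
    findInterval(u, sort(sg$start), left.open = TRUE) -
      findInterval(u, sort(sg$end), left.open = TRUE)
  }
  Y <- at_risk(seg)
  Y1 <- at_risk(seg[seg$grp == 1L, , drop = FALSE])
  dN <- as.numeric(tabulate(match(pool$exit[ev], u), nbins = length(u)))
  ev1 <- ev & grp[match(pool$id, ids)] == 1L
  dN1 <- as.numeric(tabulate(match(pool$exit[ev1], u), nbins = length(u)))

  h <- ifelse(Y > 0, Y1 / Y, 0)
  U <- sum(dN1 - h * dN)
  V <- if (variance == "hypergeometric") {
    ok <- Y > 1L
    sum((Y1 * (Y - Y1) * dN * (Y - dN) / (Y^2 * (Y - 1)))[ok])
  } else {
    sum(Y1 * (Y - Y1) * dN / Y^2)
  }
  stat <- if (V > 0) U^2 / V else 0
  if (!detail) return(stat)

  ## per-subject martingale-residual contributions to U:
  ## c_i = sum_u (g_i - h(u)) (dN_i(u) - Y_i(u) dN(u)/Y(u))
  g <- ifelse(grp == 1L, 1, 0)
  w <- ifelse(Y > 0, dN / Y, 0)
  cw <- cumsum(w); chw <- cumsum(h * w)
  ## event part
  ev_id <- as.character(pool$id[ev])
  ev_h <- h[match(pool$exit[ev], u)]
  ev_g <- g[match(pool$id[ev], ids)]
  add <- rowsum(ev_g - ev_h, ev_id)
  contrib[rownames(add)] <- contrib[rownames(add)] + add[, 1L]
  ## compensator part over each subject's state-j risk intervals
  lo <- findInterval(pmax(seg$start, s), u)
  hi <- findInterval(pmin(seg$end, tau), u)
  sw <- c(0, cw)[hi + 1L] - c(0, cw)[lo + 1L]
  shw <- c(0, chw)[hi + 1L] - c(0, chw)[lo + 1L]
  gseg <- g[match(seg$id, ids)]
  comp <- rowsum(gseg * sw - shw, as.character(seg$id))
  contrib[rownames(comp)] <- contrib[rownames(comp)] - comp[, 1L]
  list(statistic = stat, score = U, variance = V, contributions = contrib,
       empty_group = empty_group)
}

#' Grid test of the Markov property for one transition
#'
#' Computes the two-sample log-rank statistic \eqn{\mathfrak{X}_{s_i}} at
#' every landmark time of a grid and the grid statistic
#' \eqn{\mathfrak{X} = \max_i \mathfrak{X}_{s_i}}.  Its null distribution is
#' approximated by a wild bootstrap: each subject's martingale-residual
#' contribution to every score \eqn{U(s_i)} is multiplied by one i.i.d.
#' standardized compensated Poisson multiplier (\eqn{Q - 1},
#' \eqn{Q \sim} Poisson(1); mean 0, variance 1) per subject and replicate,
#' shared across grid times so the dependence structure of the maximum is
#' preserved.  The p-value uses the \eqn{(1 + \#\{\mathfrak{X}^* \ge
#' \mathfrak{X}\})/(B+1)} convention.
#'
#' @inheritParams logrank_point_statistic
#' @param grid numeric vector of landmark times.
#' @param B number of wild-bootstrap replicates.
#' @param alpha significance level for the reported decision.
#' @param seed optional integer; when supplied the RNG seed is set locally.
#' @return Object of class \code{"markov_test"}: per-grid-time statistics,
#'   the max statistic, the bootstrap null sample, \code{p_value}, the
#'   decision at \code{alpha}, and bookkeeping flags.
#' @examples
#' set.seed(1)
#' h <- simulate_histories(200, seed = 1)
#' markov_test(h, "2-1", grid = c(6, 9, 12), l1 = 2, tau = 1000, B = 99)
#' @export
markov_test <- function(x, transition, grid, l1, l2 = NULL, tau,
                        B = 500L, alpha = 0.05, seed = NULL,
                        variance = c("hypergeometric", "poisson")) {
  variance <- match.arg(variance)
  stopifnot(B >= 1L, alpha > 0, alpha < 1, length(grid) >= 1L)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ids <- unique(x$id)
  m <- length(grid)
  C <- matrix(0, length(ids), m)
  stats <- Vs <- numeric(m)
  warn <- logical(m)
  for (i in seq_len(m)) {
    d <- logrank_point_statistic(x, grid[i], transition, l1, l2, tau,
                                 variance, detail = TRUE)
    stats[i] <- d$statistic
    Vs[i] <- d$variance
    C[, i] <- d$contributions
    warn[i] <- d$empty_group
  }
  observed <- max(stats)
  G <- matrix(stats::rpois(length(ids) * B, 1) - 1, length(ids), B)
  Ustar <- crossprod(C, G)                       # m x B
  Xstar <- Ustar^2 / ifelse(Vs > 0, Vs, Inf)     # rows with V = 0 stay 0
  null <- apply(Xstar, 2L, max)
  p <- (1 + sum(null >= observed)) / (B + 1)
  structure(list(transition = as_transition_set(transition,
                                                attr(x, "state_space")),
                 grid = grid, statistics = stats, statistic = observed,
                 variances = Vs, null = null, p_value = p,
                 reject = p < alpha, alpha = alpha, B = B,
                 empty_group = warn, variance = variance),
            class = "markov_test")
}

#' @export
print.markov_test <- function(x, ...) {
  cat("Grid test of the Markov property for transition ",
      x$transition[1L, 1L], "->", x$transition[1L, 2L], "\n", sep = "")
  cat("Landmark grid:", paste(format(x$grid), collapse = ", "), "\n")
  cat("Per-time statistics:",
      paste(format(round(x$statistics, 3)), collapse = ", "), "\n")
  cat("Max statistic:", format(round(x$statistic, 3)),
      "  wild-bootstrap p-value:", format.pval(x$p_value),
      paste0("(B = ", x$B, ")\n"))
  cat(if (x$reject) "Non-Markov" else "Markov",
      "at level", x$alpha, "\n")
  if (any(x$empty_group))
    cat("Note: one group empty at grid time(s)",
        paste(format(x$grid[x$empty_group]), collapse = ", "), "\n")
  invisible(x)
}

#' Select the non-Markov transition set
#'
#' Runs the grid test on every (or a chosen subset of) permitted transition
#' and collects into \code{A} the transitions whose p-value falls below
#' \code{alpha}.  By default the first group is the origin state of the
#' tested transition and the second group all remaining states.  No
#' multiple-testing adjustment is applied: the tests are diagnostic, and
#' \code{alpha} acts per transition as the tuning parameter of the hybrid
#' estimator.  Transitions carrying no two-sample information (every
#' grid-time variance zero, e.g. because one group never occupies the origin
#' state) are reported as untestable and never selected.
#'
#' @inheritParams markov_test
#' @param transitions transitions to test (default: all in the state space).
#' @param l1 optional list (one element per tested transition) overriding
#'   the default first-group choice.
#' @return List of class \code{"nonmarkov_selection"}: \code{nonmarkov}
#'   (two-column matrix A), \code{tests} (the \code{"markov_test"} objects),
#'   \code{untestable}, \code{alpha}.
#' @export
select_nonmarkov <- function(x, grid, tau, transitions = NULL, l1 = NULL,
                             B = 500L, alpha = 0.05, seed = NULL,
                             variance = c("hypergeometric", "poisson")) {
  variance <- match.arg(variance)
  space <- attr(x, "state_space")
  transitions <- if (is.null(transitions)) space$transitions
                 else as_transition_set(transitions, space)
  nT <- nrow(transitions)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  tests <- vector("list", nT)
  untestable <- logical(nT)
  selected <- logical(nT)
  for (r in seq_len(nT)) {
    g1 <- if (is.null(l1)) transitions[r, 1L] else l1[[r]]
    tests[[r]] <- markov_test(x, transitions[r, , drop = FALSE], grid,
                              l1 = g1, tau = tau, B = B, alpha = alpha,
                              variance = variance)
    untestable[r] <- all(tests[[r]]$variances == 0)
    selected[r] <- !untestable[r] && tests[[r]]$p_value < alpha
  }
  names(tests) <- paste(transitions[, 1L], transitions[, 2L], sep = "-")
  structure(list(nonmarkov = transitions[selected, , drop = FALSE],
                 tests = tests,
                 untestable = transitions[untestable, , drop = FALSE],
                 alpha = alpha),
            class = "nonmarkov_selection")
}

#' @export
print.nonmarkov_selection <- function(x, ...) {
  p <- vapply(x$tests, `[[`, 0, "p_value")
  print(data.frame(transition = names(x$tests), p_value = p,
                   row.names = NULL))
  cat("Non-Markov set A:",
      if (nrow(x$nonmarkov))
        paste(x$nonmarkov[, 1L], x$nonmarkov[, 2L], sep = "->",
              collapse = ", ")
      else "(empty)", "\n")
  if (nrow(x$untestable))
    cat("Untestable:", paste(x$untestable[, 1L], x$untestable[, 2L],
                             sep = "->", collapse = ", "), "\n")
  invisible(x)
}
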