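#' Define a multi-state model state space
#'
#' A state space is the pair (K, E): the number of states \code{1..K} and the
#' set \code{E} of permitted direct transitions, stored as ordered pairs
#' (from, to).  States with no outgoing transition in \code{E} are absorbing.
#'
#' @param transitions two-column integer matrix (or data.frame) of permitted
#'   direct transitions, one (from, to) pair per row.
#' @param K number of states; defaults to the largest state mentioned in
#'   \code{transitions}.
#' @return An object of class \code{"state_space"}: a list with elements
#'   \code{K}, \code{transitions} (two-column matrix) and \code{absorbing}
#'   (integer vector).
#' @examples
#' state_space(rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3)))
#' @seealso [illness_death_recovery()] for the three-state model with
#'   recovery used throughout the package.
#' @export
state_space <- function(transitions, K = NULL) {
  transitions <- as.matrix(transitions)
  if (ncol(transitions) != 2L)
    stop("'transitions' must have two columns (from, to)")
  storage.mode(transitions) <- "integer"
  if (is.null(K)) K <- max(transitions)
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be a positive integer")
  if (any(transitions < 1L) || any(transitions > K))
    stop("transition states must lie in 1..", K)
  if (any(transitions[, 1L] == transitions[, 2L]))
    stop("self-transitions (j, j) are not permitted")
  if (anyDuplicated(transitions))
    stop("duplicated transition pairs")
  dimnames(transitions) <- list(NULL, c("from", "to"))
  absorbing <- setdiff(seq_len(K), unique(transitions[, 1L]))
  structure(list(K = K, transitions = transitions,
                 absorbing = as.integer(absorbing)),
            class = "state_space")
}

#' The illness-death model with recovery
#'
#' Three states with transitions 1->2, 1->3, 2->1 and 2->3; state 3 is
#' absorbing.  In the sick-leave interpretation, state 1 is employment,
#' state 2 sick leave and state 3 permanent disability.
#'
#' @return A \code{"state_space"} with K = 3.
#' @export
illness_death_recovery <- function() {
  state_space(rbind(c(1L, 2L), c(1L, 3L), c(2L, 1L), c(2L, 3L)), K = 3L)
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space with", x$K, "states\n")
  cat("Transitions:",
      paste(x$transitions[, 1L], x$transitions[, 2L], sep = "->",
            collapse = ", "), "\n")
  if (length(x$absorbing))
    cat("Absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  invisible(x)
}

## index of (from, to) rows within the transition set; NA when not a member
match_transition <- function(from, to, space) {
  match(paste(from, to), paste(space$transitions[, 1L], space$transitions[, 2L]))
}

## normalise a user-supplied set of transitions (matrix, data.frame, or
## character "j-k") into a two-column matrix, validated against the space
as_transition_set <- function(A, space) {
  if (is.null(A) || (is.atomic(A) && length(A) == 0L))
    return(space$transitions[0L, , drop = FALSE])
  if (is.character(A)) {
    parts <- strsplit(A, "-", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("transitions must look like \"j-k\"")
    A <- cbind(as.integer(vapply(parts, `[`, "", 1L)),
               as.integer(vapply(parts, `[`, "", 2L)))
  }
  A <- as.matrix(A)
  if (ncol(A) != 2L) stop("a transition set needs two columns (from, to)")
  storage.mode(A) <- "integer"
  ok <- !is.na(match_transition(A[, 1L], A[, 2L], space))
  if (!all(ok))
    stop("transitions not in the state space: ",
         paste(A[!ok, 1L], A[!ok, 2L], sep = "->", collapse = ", "))
  dimnames(A) <- list(NULL, c("from", "to"))
  A
}
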