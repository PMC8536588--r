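#' Multi-state event histories in long format
#'
#' An event-history collection is a data frame with one row per sojourn:
#' columns \code{id}, \code{entry}, \code{exit}, \code{from}, \code{to}.
#' A subject occupies state \code{from} on \code{[entry, exit)}; \code{to}
#' is the state entered at \code{exit}, with \code{to = 0} meaning the
#' observation ends at \code{exit} without a transition (censoring or the
#' administrative end of study).  A subject whose final row has
#' \code{to != 0} entered that state at \code{exit} and is taken to remain
#' there afterwards (the usual case is absorption).
#'
#' @param x data frame with columns \code{id}, \code{entry}, \code{exit},
#'   \code{from}, \code{to}.
#' @param space a [state_space()].
#' @return \code{x}, sorted by (id, entry), with class
#'   \code{"event_history"} and the state space attached as attribute
#'   \code{"state_space"}.
#' @details Validation enforces, per subject: strictly increasing sojourns
#'   (\code{entry < exit}), contiguity (each \code{entry} equals the previous
#'   \code{exit} and each \code{from} the previous \code{to}), membership of
#'   every realised transition in the transition set, and \code{to = 0} on at
#'   most the final row.  Violations are reported with the offending row
#'   numbers.
#' @examples
#' h <- toy_histories()
#' state_at(h, 0.5)
#' @export
event_history <- function(x, space) {
  stopifnot(inherits(space, "state_space"))
  need <- c("id", "entry", "exit", "from", "to")
  if (!all(need %in% names(x)))
    stop("need columns: ", paste(need, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$entry <- as.numeric(x$entry); x$exit <- as.numeric(x$exit)
  x$from <- as.integer(x$from);   x$to <- as.integer(x$to)
  ord <- order(x$id, x$entry)
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  validate_history_frame(x, space)
  structure(x, state_space = space,
            class = c("event_history", "data.frame"))
}

validate_history_frame <- function(x, space) {
  bad <- function(rows, msg) {
    if (length(rows))
      stop(msg, " (rows ", paste(utils::head(rows, 5L), collapse = ", "),
           if (length(rows) > 5L) ", ..." else "", ")", call. = FALSE)
  }
  if (nrow(x) == 0L) return(invisible(x))
  bad(which(!is.finite(x$entry) | !is.finite(x$exit) | x$entry < 0),
      "times must be finite and nonnegative")
  bad(which(x$entry >= x$exit), "'entry' must be strictly below 'exit'")
  bad(which(duplicated(x[c("id", "entry")])), "duplicate (id, entry) rows")
  bad(which(x$from < 1L | x$from > space$K), "'from' outside the state space")
  trans <- x$to != 0L
  bad(which(trans & is.na(match_transition(x$from, x$to, space))),
      "transition not in the permitted set E")
  same <- c(FALSE, x$id[-1L] == x$id[-nrow(x)])
  prev <- c(NA, seq_len(nrow(x) - 1L))
  bad(which(same & x$entry != x$exit[prev]), "non-contiguous sojourns")
  bad(which(same & x$from != x$to[prev]),
      "'from' does not match the previous 'to'")
  bad(which(!trans & c(x$id[-1L] == x$id[-nrow(x)], FALSE)),
      "'to' = 0 is only allowed on a subject's final row")
  invisible(x)
}

#' @export
print.event_history <- function(x, ...) {
  sp <- attr(x, "state_space")
  cat("Event histories:", length(unique(x$id)), "subjects,",
      sum(x$to != 0L), "transitions,", sp$K, "states\n")
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Read / write event histories as delimited text
#'
#' The file format is comma-separated with header exactly
#' \code{id,entry,exit,from,to}, one row per sojourn; the writer emits rows
#' sorted by (id, entry).
#'
#' @param path file path.
#' @param space a [state_space()].
#' @return \code{read_event_history} returns an [event_history()];
#'   \code{write_event_history} returns \code{path} invisibly.
#' @export
read_event_history <- function(path, space) {
  x <- utils::read.csv(path, colClasses = c(NA, "numeric", "numeric",
                                            "integer", "integer"))
  if (!identical(names(x), c("id", "entry", "exit", "from", "to")))
    stop("header must be exactly 'id,entry,exit,from,to'")
  event_history(x, space)
}

#' @param x an [event_history()].
#' @rdname read_event_history
#' @export
write_event_history <- function(x, path) {
  stopifnot(inherits(x, "event_history"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' A hand-checkable three-subject worked example
#'
#' Three subjects on the illness-death model with recovery: subject 1 moves
#' 1 -> 2 at t = 1, back 2 -> 1 at t = 3 and is censored at t = 5; subject 2
#' is absorbed 1 -> 3 at t = 2; subject 3 starts in state 2 and is absorbed
#' 2 -> 3 at t = 4.  Used throughout the documentation and tests because all
#' estimators can be computed by hand on it.
#'
#' @return An [event_history()] with 3 subjects and 4 transitions.
#' @export
toy_histories <- function() {
  event_history(data.frame(
    id    = c(1L, 1L, 1L, 2L, 3L),
    entry = c(0, 1, 3, 0, 0),
    exit  = c(1, 3, 5, 2, 4),
    from  = c(1L, 2L, 1L, 1L, 2L),
    to    = c(2L, 1L, 0L, 3L, 3L)),
    illness_death_recovery())
}

## Occupancy segments: state held on [start, end); a final transition row
## opens a segment [exit, Inf) in the destination state (absorption-style
## tail), while to = 0 ends observation at exit.
occupancy_segments <- function(x) {
  n <- nrow(x)
  last <- !duplicated(x$id, fromLast = TRUE)
  seg <- data.frame(id = x$id, start = x$entry, end = x$exit, state = x$from)
  tail_rows <- which(last & x$to != 0L)
  if (length(tail_rows))
    seg <- rbind(seg, data.frame(id = x$id[tail_rows],
                                 start = x$exit[tail_rows], end = Inf,
                                 state = x$to[tail_rows]))
  seg
}

#' State occupied at a time point
#'
#' Evaluates each subject's right-continuous path at time \code{s} (the state
#' AT \code{s}).  Subjects whose observation ended at or before \code{s}
#' get \code{NA}.
#'
#' @param x an [event_history()].
#' @param s time point, \code{s >= 0}.
#' @return Named integer vector, one element per subject id.
#' @export
state_at <- function(x, s) {
  stopifnot(inherits(x, "event_history"), s >= 0)
  seg <- occupancy_segments(x)
  hit <- seg$start <= s & s < seg$end
  ids <- unique(x$id)
  out <- seg$state[hit][match(ids, seg$id[hit])]
  names(out) <- as.character(ids)
  out
}

#' Landmark subsample
#'
#' Subjects occupying one of the states in \code{l} at time \code{s}
#' (right-continuous evaluation).  Subjects no longer under observation at
#' \code{s} are excluded; an empty result is legal.
#'
#' @inheritParams state_at
#' @param l integer vector of landmark states.
#' @return An [event_history()] restricted to the landmark population.
#' @export
landmark_subset <- function(x, s, l) {
  st <- state_at(x, s)
  keep <- names(st)[!is.na(st) & st %in% l]
  out <- x[as.character(x$id) %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, state_space = attr(x, "state_space"),
            class = c("event_history", "data.frame"))
}
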