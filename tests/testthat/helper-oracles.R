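# Independent brute-force oracles used to validate the vectorized
# implementations on small inputs.

# state occupied just before time t (left limit), by linear scan
oracle_state_before <- function(x, id, t) {
  rows <- x[x$id == id, , drop = FALSE]
  for (m in seq_len(nrow(rows)))
    if (rows$entry[m] < t && t <= rows$exit[m]) return(rows$from[m])
  last <- rows[nrow(rows), , drop = FALSE]
  if (last$to != 0L && t > last$exit) return(last$to)
  NA_integer_
}

# state occupied at time t (right-continuous), by linear scan
oracle_state_at <- function(x, id, t) {
  rows <- x[x$id == id, , drop = FALSE]
  for (m in seq_len(nrow(rows)))
    if (rows$entry[m] <= t && t < rows$exit[m]) return(rows$from[m])
  last <- rows[nrow(rows), , drop = FALSE]
  if (last$to != 0L && t >= last$exit) return(last$to)
  NA_integer_
}

# two-sample log-rank for transition j->k from landmark s, directly from the
# definition (per-event-time loops over subjects)
oracle_logrank <- function(x, s, jk, l1, l2, tau) {
  ids <- unique(x$id)
  grp <- vapply(ids, function(i) {
    st <- oracle_state_at(x, i, s)
    if (is.na(st)) NA_integer_
    else if (st %in% l1) 1L else if (st %in% l2) 2L else NA_integer_
  }, 0L)
  pooled <- ids[!is.na(grp)]
  if (!length(pooled)) return(0)
  ev <- x$id %in% pooled & x$from == jk[1L] & x$to == jk[2L] &
    x$exit > s & x$exit <= tau
  u <- sort(unique(x$exit[ev]))
  U <- V <- 0
  for (t in u) {
    atrisk <- vapply(pooled, function(i)
      identical(oracle_state_before(x, i, t), jk[1L]), NA)
    Y <- sum(atrisk)
    Y1 <- sum(atrisk & grp[match(pooled, ids)] == 1L)
    rows <- ev & x$exit == t
    dN <- sum(rows)
    dN1 <- sum(rows & grp[match(x$id, ids)] == 1L)
    U <- U + dN1 - Y1 * dN / Y
    if (Y > 1L) V <- V + Y1 * (Y - Y1) * dN * (Y - dN) / (Y^2 * (Y - 1))
  }
  if (V > 0) U^2 / V else 0
}

# small non-Markov-ish random cohorts for property tests
random_cohort <- function(n = 40L, seed = 1L, sigma2 = 0, tau = 60) {
  frl <- if (sigma2 > 0) frailty_gamma(sigma2) else frailty_none()
  simulate_histories(n, tau = tau, frailty = frl, seed = seed)
}
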