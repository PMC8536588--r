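test_that("frailty draws have the requested moments", {
  # degenerate gamma: all multipliers exactly one
  V0 <- draw_frailties(frailty_gamma(0), 50, seed = 1)
  expect_true(all(V0 == 1))
  V <- draw_frailties(frailty_gamma(1.2), 50000, seed = 2)
  expect_true(all(V[, c("1-2", "1-3", "2-3")] == 1))
  expect_equal(mean(V[, "2-1"]), 1, tolerance = 0.03)
  expect_equal(var(V[, "2-1"]), 1.2, tolerance = 0.05)
  VL <- draw_frailties(frailty_lognormal(), 50000, seed = 3)
  expect_equal(unname(colMeans(VL)), rep(1, 4), tolerance = 0.03)
  expect_equal(unname(apply(VL, 2, var)),
               diag(lognormal_frailty_sigma()), tolerance = 0.08)
})

test_that("an infeasible log-scale covariance is rejected with its eigenvalue", {
  expect_error(draw_frailties(frailty_lognormal(repair = FALSE), 10),
               "eigenvalue")
  # a feasible matrix needs no repair and is used as-is
  S <- diag(c(0.5, 0.5, 0.5, 0.5))
  V <- draw_frailties(frailty_lognormal(S, repair = FALSE), 20000, seed = 4)
  expect_equal(unname(apply(V, 2, var)), rep(0.5, 4), tolerance = 0.1)
})

test_that("simulated histories respect the model structure", {
  h <- simulate_histories(200, frailty = frailty_gamma(2), seed = 5)
  expect_s3_class(h, "event_history")   # constructor validates invariants
  # state 3 is absorbing: a subject's history ends at its first entry to 3
  enters3 <- h[h$to == 3L, ]
  last <- h[!duplicated(h$id, fromLast = TRUE), ]
  expect_true(all(enters3$id %in% last$id[last$to == 3L]))
  # everyone else is censored exactly at tau
  cens <- last[last$to == 0L, ]
  expect_true(all(cens$exit == 1000))
  expect_setequal(c(enters3$id, cens$id), unique(h$id))
})

test_that("zero rates yield a single censored sojourn per subject", {
  h <- simulate_histories(10, rates = c(0, 0, 0, 0), tau = 7, seed = 6)
  expect_equal(nrow(h), 10L)
  expect_true(all(h$entry == 0 & h$exit == 7 & h$from == 1L & h$to == 0L))
})

test_that("simulation is reproducible from (n, seed)", {
  h1 <- simulate_histories(50, frailty = frailty_lognormal(), seed = 123)
  h2 <- simulate_histories(50, frailty = frailty_lognormal(), seed = 123)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  h3 <- simulate_histories(50, frailty = frailty_lognormal(), seed = 124)
  expect_false(identical(as.data.frame(h1), as.data.frame(h3)))
})

test_that("without frailty the sojourn distribution matches the generator", {
  h <- simulate_histories(4000, tau = 500, seed = 7)
  first <- h[!duplicated(h$id), ]
  done <- first[first$to != 0L, ]
  # exit rate from state 1 is 0.15, destinations 0.12 : 0.03
  expect_equal(mean(done$exit), 1 / 0.15, tolerance = 0.05)
  expect_equal(mean(done$to == 2L), 0.8, tolerance = 0.05)
})

test_that("the simulation oracle recovers the Markov closed form", {
  Q <- matrix(c(-0.15, 0.12, 0.03,
                0.15, -0.25, 0.10,
                0, 0, 0), 3, 3, byrow = TRUE)
  grid <- seq(2, 30, by = 2)
  orc <- true_probability_oracle(0, 1, reps = 10, n = 2000, tau = 40,
                                 seed = 8, grid = grid)
  truth <- t(vapply(grid, function(t)
    as.matrix(Matrix::expm(t * Q))[1, ], numeric(3)))
  expect_lt(max(abs(orc$probs - truth)), 0.03)
  # probability rows, and reps = 1 equals a single landmark estimate
  expect_true(all(abs(rowSums(orc$probs) - 1) < 1e-12))
  one <- true_probability_oracle(0, 1, reps = 1, n = 200, tau = 40,
                                 seed = 9, grid = grid)
  h <- simulate_histories(200, tau = 40, seed = 9)
  fit <- transprob(h, 0, 1, 40, "lmaj")
  expect_equal(unname(one$probs), unname(predict(fit, grid)))
})
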