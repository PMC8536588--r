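test_that("worked-example transition probabilities match hand products", {
  h <- toy_histories()
  aj <- transprob(h, 0, 1, 5, "aj")
  expect_equal(unname(predict(aj, 4)[1, ]), c(0.25, 0, 0.75))
  lmaj <- transprob(h, 0.5, 1, 5, "lmaj")
  expect_equal(unname(predict(lmaj, 4)[1, ]), c(0.5, 0, 0.5))
  haj <- transprob(h, 0.5, 1, 5, "haj", nonmarkov = "2-1")
  expect_equal(unname(predict(haj, 4)[1, ]), c(0.5, 0, 0.5))
  # value at the landmark time is the unit vector of the landmark state
  expect_equal(unname(aj$probs[1, ]), c(1, 0, 0))
  expect_equal(aj$times[1], 0)
})

test_that("the hybrid estimator interpolates AJ and LMAJ exactly", {
  h <- random_cohort(n = 60L, seed = 2L, sigma2 = 2)
  s <- 10; tau <- 60
  aj <- transprob(h, s, 2, tau, "aj")
  lmaj <- transprob(h, s, 2, tau, "lmaj")
  haj0 <- transprob(h, s, 2, tau, "haj", nonmarkov = NULL)
  hajE <- transprob(h, s, 2, tau, "haj",
                    nonmarkov = illness_death_recovery()$transitions)
  expect_identical(haj0$probs, aj$probs)
  expect_identical(haj0$times, aj$times)
  grid <- seq(s, tau, by = 2.5)
  expect_identical(predict(hajE, grid), predict(lmaj, grid))
})

test_that("hazard merging and risk-set removal give the same estimator", {
  for (seed in c(3L, 8L)) {
    h <- random_cohort(n = 40L, seed = seed, sigma2 = 1.2)
    s <- 8; tau <- 60; A <- "2-1"
    merged <- transprob(h, s, 2, tau, "haj", nonmarkov = A)$hazard
    removed <- hajmsm:::haj_hazard_by_removal(h, s, 2, tau, A)
    expect_identical(merged$times, removed$times)
    expect_identical(merged$delta, removed$delta)
  }
})

test_that("curves are probability vectors at every evaluation time", {
  for (seed in 1:4) {
    h <- random_cohort(n = 50L, seed = seed, sigma2 = 2)
    for (m in c("aj", "lmaj", "haj")) {
      fit <- transprob(h, 6, 2, 60, m, nonmarkov = if (m == "haj") "2-1")
      expect_true(all(fit$probs > -1e-12 & fit$probs < 1 + 1e-12))
      expect_true(all(abs(rowSums(fit$probs) - 1) < 1e-12))
    }
  }
})

test_that("bookkeeping identity: landmark curve equals occupancy fractions", {
  # with complete observation up to tau, e_l P^LM(s, t) must equal the
  # landmark occupation fractions Ybar^LM(t+)/Ybar^LM(s) exactly
  for (seed in 1:10) {
    h <- random_cohort(n = 25L, seed = seed + 100L, sigma2 = 2, tau = 80)
    s <- 8
    for (l in 1:2) {
      lmh <- landmark_subset(h, s, l)
      if (!nrow(lmh)) next
      fit <- transprob(h, s, l, 80, "lmaj")
      n_lm <- length(unique(lmh$id))
      for (t in fit$times[fit$times < 80]) {
        frac <- tabulate(state_at(lmh, t), nbins = 3L) / n_lm
        expect_equal(unname(predict(fit, t)[1, ]), frac, tolerance = 1e-12)
      }
    }
  }
})

test_that("occupation probabilities equal empirical fractions when uncensored", {
  h <- toy_histories()
  expect_equal(unname(occupation_probabilities(h, 0)$probs[1, ]),
               c(2, 1, 0) / 3)
  occ <- occupation_probabilities(h, 4)
  expect_equal(unname(predict(occ, 4)[1, ]), c(1, 0, 2) / 3)
  for (seed in 1:5) {
    h <- random_cohort(n = 30L, seed = seed + 50L, sigma2 = 1.2, tau = 80)
    occ <- occupation_probabilities(h, 70)
    n <- length(unique(h$id))
    for (t in c(5, 20, 45, 70)) {
      frac <- tabulate(state_at(h, t), nbins = 3L) / n
      expect_equal(unname(predict(occ, t)[1, ]), frac, tolerance = 1e-12)
    }
  }
  empty <- event_history(data.frame(id = integer(), entry = numeric(),
                                    exit = numeric(), from = integer(),
                                    to = integer()),
                         illness_death_recovery())
  expect_error(occupation_probabilities(empty, 1), "no subjects")
})

test_that("degenerate inputs give constant curves", {
  h <- toy_histories()
  # empty landmark population: curve stays at e_l
  fit <- transprob(h, 4.5, 2, 5, "lmaj")
  expect_true(all(fit$probs[, 2] == 1))
  # zero hazard (no events in window)
  fit2 <- transprob(h, 4, 1, 5, "aj")
  expect_equal(nrow(fit2$probs), 1L)
  expect_equal(unname(fit2$probs[1, ]), c(1, 0, 0))
  # subjects that never move: unit vector forever
  still <- event_history(data.frame(id = 1:3, entry = 0, exit = 10,
                                    from = 1L, to = 0L),
                         illness_death_recovery())
  occ <- occupation_probabilities(still, 9)
  expect_true(all(predict(occ, c(1, 5, 9))[, 1] == 1))
})

test_that("landmark risk sets never exceed full-sample risk sets", {
  h <- random_cohort(n = 50L, seed = 77L, sigma2 = 2)
  s <- 10; tau <- 60
  full <- aggregate_processes(h, c(s, tau))
  lmh <- landmark_subset(h, s, 2)
  lm <- aggregate_processes(lmh, c(s, tau))
  ix <- match(lm$times, full$times)
  expect_false(anyNA(ix))
  expect_true(all(lm$n_risk <= full$n_risk[ix, , drop = FALSE]))
})

test_that("prediction follows the right-continuous step convention", {
  h <- toy_histories()
  fit <- transprob(h, 0, 1, 5, "aj")
  # between jumps the curve holds the value of the previous jump
  expect_equal(unname(predict(fit, 2.5)), unname(predict(fit, 2)))
  expect_equal(unname(predict(fit, 3.999)), unname(predict(fit, 3)))
  # before the first jump it holds the initial vector
  expect_equal(unname(predict(fit, 0.5)[1, ]), c(1, 0, 0))
})
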