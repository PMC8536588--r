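test_that("single-jump two-sample statistic matches the hand computation", {
  sp <- illness_death_recovery()
  # one subject per group at risk in state 2, the event in group 1:
  # U = 1 - 1/2, V = 1/4, statistic = 1
  h <- event_history(data.frame(id = c(1, 2, 2),
                                entry = c(0, 0, 1), exit = c(2, 1, 5),
                                from = c(2, 1, 2), to = c(1, 2, 0)), sp)
  d <- logrank_point_statistic(h, 0.5, "2-1", l1 = 2, l2 = 1, tau = 5,
                               detail = TRUE)
  expect_equal(d$score, 0.5)
  expect_equal(d$variance, 0.25)
  expect_equal(d$statistic, 1)
  # contributions decompose the score
  expect_equal(sum(d$contributions), d$score)
})

test_that("perfectly balanced groups give a zero statistic", {
  sp <- illness_death_recovery()
  # pairs: one subject per group, at risk in state 2 over the same window
  # and with 2->1 events at identical times -> every term cancels
  rows <- list()
  for (p in 1:3) {
    tev <- 3 + p
    rows[[2 * p - 1]] <- data.frame(id = 10 + p, entry = 0, exit = tev,
                                    from = 2, to = 1)
    rows[[2 * p]] <- data.frame(id = 20 + p,
                                entry = c(0, 1.5), exit = c(1.5, tev),
                                from = c(1, 2), to = c(2, 1))
  }
  h <- event_history(do.call(rbind, rows), sp)
  stat <- logrank_point_statistic(h, 1, "2-1", l1 = 2, l2 = 1, tau = 10)
  expect_equal(stat, 0)
})

test_that("degenerate windows and empty groups return zero", {
  h <- toy_histories()
  expect_equal(logrank_point_statistic(h, 4.2, "2-3", l1 = 2, l2 = 1,
                                       tau = 5), 0)
  d <- logrank_point_statistic(h, 4.5, "2-1", l1 = 2, l2 = 1, tau = 5,
                               detail = TRUE)
  expect_true(d$empty_group)
  expect_equal(d$statistic, 0)
  expect_error(logrank_point_statistic(h, 1, "2-1", l1 = 2, l2 = 2, tau = 5),
               "disjoint")
})

test_that("the vectorized statistic agrees with the brute-force oracle", {
  for (seed in 1:6) {
    h <- random_cohort(n = 35L, seed = seed + 10L, sigma2 = 2, tau = 60)
    for (s in c(5, 12)) {
      got <- logrank_point_statistic(h, s, "2-1", l1 = 2, l2 = 1, tau = 60)
      want <- oracle_logrank(h, s, c(2L, 1L), 2L, 1L, 60)
      expect_equal(got, want, tolerance = 1e-12)
      got2 <- logrank_point_statistic(h, s, "1-2", l1 = 1, l2 = 2, tau = 60)
      want2 <- oracle_logrank(h, s, c(1L, 2L), 1L, 2L, 60)
      expect_equal(got2, want2, tolerance = 1e-12)
    }
  }
})

test_that("score contributions always sum to the score", {
  for (seed in 1:4) {
    h <- random_cohort(n = 40L, seed = seed, sigma2 = 1.2, tau = 60)
    d <- logrank_point_statistic(h, 9, "2-1", l1 = 2, l2 = 1, tau = 60,
                                 detail = TRUE)
    expect_equal(sum(d$contributions), d$score, tolerance = 1e-10)
  }
})

test_that("the statistic is invariant to relabeling and time shifts", {
  h <- random_cohort(n = 30L, seed = 21L, sigma2 = 2, tau = 60)
  base <- logrank_point_statistic(h, 8, "2-1", l1 = 2, l2 = 1, tau = 60)
  sp <- illness_death_recovery()
  shuf <- as.data.frame(h)
  shuf$id <- match(shuf$id, sample(unique(shuf$id)))
  relab <- event_history(shuf, sp)
  expect_equal(logrank_point_statistic(relab, 8, "2-1", l1 = 2, l2 = 1,
                                       tau = 60), base)
  shift <- as.data.frame(h)
  shift$entry <- shift$entry + 5; shift$exit <- shift$exit + 5
  shifted <- event_history(shift, sp)
  expect_equal(logrank_point_statistic(shifted, 13, "2-1", l1 = 2, l2 = 1,
                                       tau = 65), base)
})

test_that("the grid test maximises per-time statistics and is deterministic", {
  h <- random_cohort(n = 120L, seed = 31L, sigma2 = 2, tau = 200)
  grid <- c(5, 8, 11, 14)
  mt <- markov_test(h, "2-1", grid = grid, l1 = 2, l2 = 1, tau = 200,
                    B = 99, seed = 7)
  expect_equal(mt$statistic, max(mt$statistics))
  expect_true(all(mt$statistic >= mt$statistics))
  pts <- vapply(grid, function(s)
    logrank_point_statistic(h, s, "2-1", l1 = 2, l2 = 1, tau = 200), 0)
  expect_equal(mt$statistics, pts)
  expect_true(mt$p_value >= 1 / 100 && mt$p_value <= 1)
  mt2 <- markov_test(h, "2-1", grid = grid, l1 = 2, l2 = 1, tau = 200,
                     B = 99, seed = 7)
  expect_identical(mt$p_value, mt2$p_value)
  expect_identical(mt$null, mt2$null)
})

test_that("no information means p-value one", {
  h <- toy_histories()
  mt <- markov_test(h, "2-3", grid = c(4.2, 4.4), l1 = 2, l2 = 1, tau = 5,
                    B = 50, seed = 1)
  expect_equal(mt$statistic, 0)
  expect_equal(mt$p_value, 1)
})

test_that("selection flags a strong frailty transition and reports untestable ones", {
  h <- simulate_histories(1000, frailty = frailty_gamma(2), seed = 99)
  sel <- select_nonmarkov(h, grid = c(6, 9, 12, 14, 17, 20, 22, 25, 28, 30),
                          tau = 1000, B = 200, seed = 13)
  expect_true("2-1" %in% paste(sel$nonmarkov[, 1], sel$nonmarkov[, 2],
                               sep = "-"))
  # a dataset where state 1 is never revisited from state 2 makes the
  # origin-2 transitions untestable for the group starting in state 1
  sp <- illness_death_recovery()
  h2 <- event_history(data.frame(id = 1:4, entry = 0, exit = c(2, 3, 4, 5),
                                 from = c(1, 1, 2, 2), to = c(3, 3, 3, 3)),
                      sp)
  sel2 <- select_nonmarkov(h2, grid = 1, tau = 6, B = 20, seed = 3)
  expect_equal(nrow(sel2$nonmarkov), 0L)
  expect_true(nrow(sel2$untestable) == 4L)
})
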