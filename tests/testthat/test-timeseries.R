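test_that("binarize uses a strict threshold and preserves length", {
  y <- binarize(accel_series(c(50, 10, 41, 40)), threshold_mg = 40)
  expect_equal(y$states, c("active", "rest", "active", "rest"))
  expect_length(y, 4L)

  zeros <- binarize(accel_series(rep(0, 20)), threshold_mg = 5)
  expect_true(all(zeros$states == "rest"))
})

test_that("binarize active fraction matches the uniform law of large numbers", {
  set.seed(11)
  x <- accel_series(runif(1e5, 0, 80))
  y <- binarize(x, 40)
  expect_equal(mean(y$states == "active"), 0.5, tolerance = 0.01)
})

test_that("binarize is monotone in the threshold", {
  set.seed(12)
  x <- accel_series(runif(500, 0, 100))
  lo <- binarize(x, 30)$states == "active"
  hi <- binarize(x, 60)$states == "active"
  expect_true(all(lo | !hi))  # raising the threshold never activates an epoch
})

test_that("invalid acceleration values are reported by epoch index", {
  expect_error(accel_series(c(1, 2, NaN, 4)), "epoch 3")
  expect_error(accel_series(c(1, -2)), "epoch 2")
  expect_error(state_series(c("a", "x")), "epoch 2")
})

test_that("hourly proportions aggregate aligned blocks and refuse truncation", {
  y <- state_series(rep(c("a", "r"), each = 30))
  expect_equal(hourly_proportions(y, 60)$values, 0.5)

  y2 <- state_series(rep("a", 120))
  expect_equal(hourly_proportions(y2, 60)$values, c(1, 1))

  y3 <- random_states(10080)
  p <- hourly_proportions(y3, 60)
  expect_length(p, 168L)
  expect_equal(p$days, 7L)

  expect_error(hourly_proportions(state_series(rep("a", 61)), 60),
               "not divisible")
})

test_that("bout extraction reproduces the worked-example tallies", {
  b <- extract_bouts(example_sequence())
  expect_equal(b$rest_bouts, c(2, 1, 2, 2))
  expect_equal(b$activity_bouts, c(3, 1, 3, 1))
  k <- bout_counts(b)
  expect_equal(k[c("n_r", "n_r_star", "n_a", "n_a_star")],
               list(n_r = 4L, n_r_star = 3L, n_a = 4L, n_a_star = 4L))
  expect_equal(k[c("T_r", "T_r_star", "T_a", "T_a_star")],
               list(T_r = 7, T_r_star = 6, T_a = 8, T_a_star = 8))
  expect_equal(k$S_r, 2L)
  expect_equal(k$S_a, 3L)
})

test_that("bout extraction handles the single-epoch edge case", {
  b <- extract_bouts(state_series("r"))
  expect_equal(b$rest_bouts, 1L)
  expect_length(b$activity_bouts, 0L)
  k <- bout_counts(b)
  expect_equal(k$n_r, 1L)
  expect_equal(k$n_r_star, 0L)
  expect_equal(k$T_r_star, 0)
})

test_that("bout decomposition round-trips and conserves time", {
  set.seed(21)
  for (i in 1:20) {
    y <- random_states(sample(50:1000, 1), p_active = runif(1, 0.2, 0.8))
    b <- extract_bouts(y)
    expect_equal(sum(b$rest_bouts) + sum(b$activity_bouts), length(y))
    expect_equal(expand_bouts(b)$states, y$states)
    k <- bout_counts(b)
    expect_lte(abs(k$n_r - k$n_a), 1L)
  }
})

test_that("survival counts match brute force on the worked example", {
  b <- extract_bouts(example_sequence())
  s <- survival_counts(b, "rest")
  expect_equal(s$N, c(4, 3))
  expect_equal(s$delta, c(1, 3))
  sc <- survival_counts(b, "rest", corrected = TRUE)
  expect_equal(sc$N, c(3, 2))
  expect_equal(sc$delta, c(1, 2))
})

test_that("survival counts are monotone and conserve totals on random input", {
  set.seed(22)
  for (i in 1:20) {
    b <- extract_bouts(random_states(400))
    for (st in c("rest", "active")) {
      s <- survival_counts(b, st)
      expect_true(all(diff(s$N) <= 0))
      expect_true(all(s$delta >= 0))
      k <- bout_counts(b)
      expect_equal(s$N[1], if (st == "rest") k$n_r else k$n_a)
      expect_equal(sum(s$delta), s$N[1])
      # sum over s of s * (#bouts of exact length s) = total time in state
      expect_equal(sum(s$s * s$delta), if (st == "rest") k$T_r else k$T_a)
    }
  }
})

test_that("survival counts refuse an absent state", {
  b <- extract_bouts(state_series(rep("a", 10)))
  expect_error(survival_counts(b, "rest"), "no rest bouts")
  b1 <- extract_bouts(state_series("r"))
  expect_error(survival_counts(b1, "rest", corrected = TRUE), "corrected")
})

test_that("window splitting treats each window as an independent sequence", {
  y <- state_series(c(rep("a", 5), rep("r", 5)))
  w <- window_map(c(0, 5), c(5, 10), c("awake", "sleep"))
  sp <- split_by_windows(y, w)
  expect_equal(sp$awake$counts$n_a, 1L)
  expect_equal(sp$awake$counts$n_a_star, 0L)  # terminal in its window
  expect_equal(sp$sleep$counts$n_r, 1L)
  expect_equal(sp$sleep$counts$n_r_star, 0L)

  # an activity bout spanning the boundary is cut into two bouts
  y2 <- state_series(c("r", "r", "r", "a", "a", "a", "a", "r", "r", "r"))
  sp2 <- split_by_windows(y2, w)
  expect_equal(sp2$awake$bouts[[1]]$activity_bouts, 2L)
  expect_equal(sp2$sleep$bouts[[1]]$activity_bouts, 2L)
  expect_equal(sp2$awake$counts$n_a_star, 0L)  # cut bout ends its window
  expect_equal(sp2$sleep$counts$n_a_star, 1L)
})

test_that("a single awake window reproduces the unsplit decomposition", {
  y <- example_sequence()
  sp <- split_by_windows(y, window_map(0, 15, "awake"))
  k_split <- sp$awake$counts
  k_full <- bout_counts(extract_bouts(y))
  for (f in names(k_split)) expect_equal(k_split[[f]], k_full[[f]], info = f)
  expect_equal(sp$sleep$counts$n_r_star, 0L)
})

test_that("window maps reject gaps, overlaps and bad labels", {
  y <- state_series(rep(c("a", "r"), 5))
  expect_error(split_by_windows(y, window_map(c(0, 6), c(5, 10),
                                              c("awake", "sleep"))),
               "gaps")
  expect_error(window_map(c(0, 4), c(5, 10), c("awake", "sleep")), "overlap")
  expect_error(window_map(0, 5, "day"), "awake")
  expect_error(window_map(c(0, 5), c(5, 10), c("awake", "awake")),
               "alternate")
})
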