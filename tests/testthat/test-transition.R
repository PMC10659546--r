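test_that("order-1 estimators reproduce the worked example", {
  b <- extract_bouts(example_sequence())
  ml <- tp_ml_order1(b)
  expect_equal(ml$pi_ra, 0.5)
  expect_equal(ml$pi_ar, 0.5)
  rd <- rad(b)
  expect_equal(rd$pi_ra, 4 / 7)
  expect_equal(round(rd$pi_ra, 2), 0.57)
  expect_equal(rd$pi_ar, 0.5)
  by <- tp_bayes_order1(b, 0.5)
  expect_equal(by$pi_ra, 3.5 / 6.5)
  expect_equal(by$pi_ar, 4.5 / 8.5)
  expect_equal(round(c(by$pi_ra, by$pi_ar), 2), c(0.54, 0.53))
})

test_that("ML handles a single observed transition and censored states", {
  y <- state_series(c(rep("r", 9), "a"))
  expect_warning(ml <- tp_ml_order1(extract_bouts(y)), "NA")
  expect_equal(ml$pi_ra, 1 / 9)
  expect_true(is.na(ml$pi_ar))  # the only activity bout is censored

  all_r <- extract_bouts(state_series(rep("r", 10)))
  ml_r <- suppressWarnings(tp_ml_order1(all_r))
  expect_equal(ml_r$pi_ra, 0)
  expect_true(is.na(ml_r$pi_ar))
  expect_error(tp_ml_order1(extract_bouts(state_series("r"))), "undefined")
  expect_error(rad(all_r), "absent")
  # Bayes is always defined; the missing state transitions out with prob. 1
  by <- tp_bayes_order1(all_r, 0.5)
  expect_equal(by$pi_ar, 1)
  expect_error(tp_bayes_order1(all_r, 0), "positive")
})

test_that("order-1 ML recovers simulated Markov transition probabilities", {
  m <- gen_markov_states(0.1, 0.3, T_len = 10080, seed = 41)
  ml <- tp_ml_order1(extract_bouts(m))
  expect_equal(ml$pi_ra, 0.1, tolerance = 0.2)
  expect_equal(ml$pi_ar, 0.3, tolerance = 0.067)
  expect_lt(abs(ml$pi_ra - 0.1), 0.02)
  expect_lt(abs(ml$pi_ar - 0.3), 0.02)
})

test_that("Bayes converges to ML as lambda shrinks (sup over sequences)", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    b <- extract_bouts(random_states(sample(30:300, 1)))
    k <- bout_counts(b)
    if (k$T_r_star < 1 || k$T_a_star < 1) next
    ml <- tp_ml_order1(b)
    by <- tp_bayes_order1(b, 1e-6)
    worst <- max(worst, abs(by$pi_ra - ml$pi_ra), abs(by$pi_ar - ml$pi_ar))
  }
  expect_lt(worst, 1e-4)
})

test_that("RAD sandwiches ML according to the terminal state", {
  set.seed(43)
  for (i in 1:100) {
    b <- extract_bouts(random_states(sample(30:300, 1)))
    k <- bout_counts(b)
    if (k$T_r_star < 1 || k$T_a_star < 1) next
    ml <- tp_ml_order1(b)
    rd <- rad(b)
    if (b$last_state == "rest") {
      expect_equal(rd$pi_ar, ml$pi_ar)
      expect_gte(rd$pi_ra, ml$pi_ra)
      if (k$T_r > k$n_r) expect_gt(rd$pi_ra, ml$pi_ra)
    } else {
      expect_equal(rd$pi_ra, ml$pi_ra)
      expect_gte(rd$pi_ar, ml$pi_ar)
      if (k$T_a > k$n_a) expect_gt(rd$pi_ar, ml$pi_ar)
    }
  }
})

test_that("duration-dependent ML curve matches brute force on the example", {
  b <- extract_bouts(example_sequence())
  cu <- tp_ml_duration(b, "ra")
  expect_equal(cu$s_values, 1L)
  expect_equal(cu$probabilities, 1 / 3)
  expect_true(all(cu$probabilities >= 0 & cu$probabilities <= 1))
})

test_that("the duration curve is flat for geometric (Markov) bout lengths", {
  m <- gen_markov_states(0.2, 0.4, T_len = 1e5, seed = 44)
  cu <- tp_ml_duration(extract_bouts(m), "ra")
  early <- cu$probabilities[cu$s_values <= 5]
  expect_true(all(abs(early - 0.2) < 0.03))
})

test_that("semi-Markov durations give a non-flat, non-monotone ML curve", {
  y <- gen_semi_markov_states(2e4, seed = 45)
  b <- extract_bouts(y)
  cu <- tp_ml_duration(b, "ra")
  surv <- survival_counts(b, "rest", corrected = TRUE)
  solid <- cu$probabilities[cu$s_values %in% surv$s[surv$N >= 30]]
  expect_gt(max(solid) - min(solid), 0.05)        # memoryful: not flat
  expect_true(any(diff(solid) > 0) && any(diff(solid) < 0))  # non-monotone
})

test_that("constant bout durations concentrate the curve at the endpoint", {
  y <- state_series(rep(rep(c("r", "a"), each = 5), 20))
  cu <- tp_ml_duration(extract_bouts(y), "ra")
  expect_true(all(cu$probabilities[cu$s_values < 5] == 0))
})

test_that("heuristic curve matches the example and equals ML when d = 1", {
  b <- extract_bouts(example_sequence())  # terminal state is rest
  h <- tp_heuristic_duration(b, "ar")
  expect_equal(h$probabilities[h$s_values == 1], 0.5)
  expect_equal(h$d_values[h$s_values == 1], 1L)
  ml <- tp_ml_duration(b, "ar")
  expect_equal(h$probabilities[h$s_values == 1],
               ml$probabilities[ml$s_values == 1])
  expect_true(all(h$probabilities > 0 & h$probabilities < 1))
})

test_that("heuristic d = 1 equality with ML holds on random sequences", {
  set.seed(46)
  checked <- 0
  for (i in 1:100) {
    b <- extract_bouts(random_states(sample(50:400, 1)))
    # the equality is stated for the direction whose origin state is not
    # terminal (correction then leaves the survival counts unchanged)
    dir <- if (b$last_state == "rest") "ar" else "ra"
    h <- try(tp_heuristic_duration(b, dir), silent = TRUE)
    m <- try(tp_ml_duration(b, dir), silent = TRUE)
    if (inherits(h, "try-error") || inherits(m, "try-error")) next
    common <- intersect(h$s_values[h$d_values == 1], m$s_values)
    if (length(common) == 0) next
    expect_equal(h$probabilities[match(common, h$s_values)],
                 m$probabilities[match(common, m$s_values)])
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("gapped bout-length distributions force d > 1 heuristic points", {
  # bouts of length 2 or 10 only: survival is flat on 3..10
  y <- gen_semi_markov_states(
    5000,
    rest_dur = function(n) sample(c(2, 10), n, replace = TRUE),
    active_dur = function(n) sample(c(2, 10), n, replace = TRUE),
    seed = 47)
  h <- tp_heuristic_duration(extract_bouts(y), "ra")
  expect_true(any(h$d_values > 1))
  expect_true(all(h$probabilities > 0 & h$probabilities < 1))
})

test_that("uniform bout length L exercises the d > 1 bridging rule", {
  y <- state_series(rep(rep(c("r", "a"), each = 4), 10))
  h <- tp_heuristic_duration(extract_bouts(y), "ra")
  # N(s) = n on 1..4, 0 after: minimal d bridges to L + 1
  expect_equal(h$d_values, c(4L, 3L, 2L))
  expect_equal(h$probabilities, 1 / c(4, 3, 2))
})

test_that("weighted summary returns the closed form on the worked example", {
  b <- extract_bouts(example_sequence())
  w <- tp_weighted_summary(b, "ra")
  expect_equal(as.numeric(w), 0.25)  # (3 - 2) / (6 - 2)
})

test_that("closed form equals the explicit weighted sum when uncensored", {
  set.seed(48)
  checked <- 0
  for (i in 1:50) {
    b <- extract_bouts(random_states(sample(100:500, 1)))
    dir <- if (b$last_state == "rest") "ar" else "ra"  # origin not terminal
    w <- try(tp_weighted_summary(b, dir), silent = TRUE)
    if (inherits(w, "try-error")) next
    expect_equal(as.numeric(w), attr(w, "weighted_sum"))
    checked <- checked + 1
  }
  expect_gt(checked, 30)
})

test_that("weighted summary approximates order-1 ML on long Markov chains", {
  m <- gen_markov_states(0.15, 0.3, T_len = 10080, seed = 49)
  b <- extract_bouts(m)
  ml <- tp_ml_order1(b)
  k <- bout_counts(b)
  for (dir in c("ra", "ar")) {
    w <- tp_weighted_summary(b, dir)
    target <- if (dir == "ra") ml$pi_ra else ml$pi_ar
    expect_lt(abs(as.numeric(w) - target), 0.01)
  }
  # the approximation regime holds: many more bouts than maximal-length ones
  surv_r <- survival_counts(b, "rest", corrected = TRUE)
  expect_gte(k$n_r_star, 100 * surv_r$N[nrow(surv_r)])
})

test_that("weighted summary rejects the degenerate single-short-bout case", {
  y <- state_series(c("a", "r", "a", "r"))  # all bouts length 1
  expect_error(tp_weighted_summary(extract_bouts(y), "ra"), "not positive")
})

test_that("window TPs reduce to whole-series Bayes for one awake window", {
  y <- example_sequence()
  tp <- window_tp(y, window_map(0, 15, "awake"), lambda = 0.5)
  by <- tp_bayes_order1(extract_bouts(y), 0.5)
  expect_equal(tp$tp_ra_w, by$pi_ra)
  expect_equal(tp$tp_ar_w, by$pi_ar)
  # empty sleep class: both sleep TPs hit the missing-state rule
  expect_equal(tp$tp_ra_s, 1)
  expect_equal(tp$tp_ar_s, 1)
})

test_that("a sleep window without activity yields TP_ar_s = 1", {
  sim <- gen_weekly_profile(sleep_active_rate = 0, seed = 50)
  tp <- window_tp(sim$states, sim$windows)
  expect_equal(tp$tp_ar_s, 1)
})

test_that("window TPs recover simulated window-specific probabilities", {
  sim <- gen_weekly_profile(tp_awake = c(ra = 0.10, ar = 0.28),
                            tp_sleep = c(ra = 0.007, ar = 0.77),
                            seed = 51)
  tp <- window_tp(sim$states, sim$windows, lambda = 0.5)
  expect_equal(tp$tp_ra_w, 0.10, tolerance = 0.15)
  expect_equal(tp$tp_ar_w, 0.28, tolerance = 0.15)
  expect_equal(tp$tp_ra_s, 0.007, tolerance = 0.5)
  expect_equal(tp$tp_ar_s, 0.77, tolerance = 0.15)
  # expected physiological ordering
  expect_gt(tp$tp_ar_s, tp$tp_ar_w)
  expect_gt(tp$tp_ra_w, tp$tp_ra_s)
})

test_that("window TP lambda is restricted to (0, 1]", {
  y <- example_sequence()
  w <- window_map(0, 15, "awake")
  expect_error(window_tp(y, w, lambda = 0), "\\(0, 1\\]")
  expect_error(window_tp(y, w, lambda = 1.5), "\\(0, 1\\]")
  expect_silent(window_tp(y, w, lambda = 1))
})
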