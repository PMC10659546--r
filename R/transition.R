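# Transition-probability estimators for the two-state rest/activity chain.
#
# Four families: order-1 maximum likelihood on the corrected (starred)
# tallies, the Beta-Binomial Bayesian estimator that is always defined,
# the uncorrected reciprocal-average-duration ratios, and the
# duration-dependent curve (ML and heuristic) with its weighted-mean
# summary.  The headline per-individual metrics are the four Bayesian TPs
# split by awake/sleep windows.

new_tp_order1 <- function(pi_ra, pi_ar, estimator, lambda = NULL) {
  structure(
    list(pi_ra = pi_ra, pi_ar = pi_ar, estimator = estimator,
         lambda = lambda),
    class = "tp_order1"
  )
}

#' @export
print.tp_order1 <- function(x, ...) {
  cat(sprintf("<tp_order1 %s%s> rest->active %.4f, active->rest %.4f\n",
              x$estimator,
              if (is.null(x$lambda)) "" else sprintf(" lambda=%g", x$lambda),
              x$pi_ra, x$pi_ar))
  invisible(x)
}

#' Order-1 transition probabilities, maximum likelihood
#'
#' Per-epoch switch probabilities estimated from the corrected bout
#' tallies: rest-to-active as `n_r*/T_r*` and active-to-rest as
#' `n_a*/T_a*`.  The correction removes the terminal bout's unobservable
#' transition from both numerator and denominator.
#'
#' @param bouts A `bout_decomposition` from [extract_bouts()].
#' @return A `tp_order1` with `pi_ra`, `pi_ar`.  A direction whose origin
#'   state has no corrected observation time is `NA` with a warning
#'   ([tp_bayes_order1()] is always defined); if neither direction is
#'   estimable an error is raised.
#' @examples
#' y <- state_series(c("a","a","a","r","r","a","r","a","a","a","r","r","a","r","r"))
#' tp_ml_order1(extract_bouts(y))  # 0.50 / 0.50
#' @export
tp_ml_order1 <- function(bouts) {
  k <- bout_counts(bouts)
  if (k$T_r_star < 1L && k$T_a_star < 1L) {
    stop(paste0("ML order-1 estimator undefined: no corrected observation ",
                "time in either state (use tp_bayes_order1)"), call. = FALSE)
  }
  pi_ra <- NA_real_
  pi_ar <- NA_real_
  if (k$T_r_star >= 1L) pi_ra <- k$n_r_star / k$T_r_star
  if (k$T_a_star >= 1L) pi_ar <- k$n_a_star / k$T_a_star
  if (anyNA(c(pi_ra, pi_ar))) {
    warning(paste0("a state has no corrected observation time; its ML ",
                   "estimate is NA (tp_bayes_order1 is always defined)"))
  }
  new_tp_order1(pi_ra, pi_ar, "ML")
}

#' Order-1 transition probabilities, Bayesian (Beta-Binomial)
#'
#' Posterior point estimates `(n* + lambda) / (T* + lambda)` with a
#' symmetric pseudo-count prior.  Always defined: when a state is entirely
#' absent the estimate is `lambda/lambda = 1`, encoding that a visit to
#' the missing state would immediately revert.  `lambda = 0.5` is the
#' Horseshoe-style default, `lambda = 1` the uniform prior, and tiny
#' values recover the ML estimate numerically.
#'
#' @param bouts A `bout_decomposition`.
#' @param lambda Positive prior pseudo-count.
#' @return A `tp_order1`.
#' @export
tp_bayes_order1 <- function(bouts, lambda = 0.5) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("lambda must be a single positive number", call. = FALSE)
  }
  k <- bout_counts(bouts)
  new_tp_order1((k$n_r_star + lambda) / (k$T_r_star + lambda),
                (k$n_a_star + lambda) / (k$T_a_star + lambda),
                "Bayes", lambda = lambda)
}

#' Reciprocal average duration (RAD)
#'
#' Uncorrected bout-count-to-time ratios `n_r/T_r` and `n_a/T_a`: the
#' reciprocal of the mean bout duration per state.  For the state ending
#' the series RAD counts a transition that was never observed, so it
#' exceeds the corrected ML estimate for that direction and equals it for
#' the other.
#'
#' @param bouts A `bout_decomposition`.
#' @return A `tp_order1` with estimator `"RAD"`.
#' @export
rad <- function(bouts) {
  k <- bout_counts(bouts)
  if (k$T_r < 1L || k$T_a < 1L) {
    stop("RAD undefined: a state is absent from the series", call. = FALSE)
  }
  new_tp_order1(k$n_r / k$T_r, k$n_a / k$T_a, "RAD")
}

direction_state <- function(direction) {
  # origin state of the transition: ra leaves rest, ar leaves activity
  switch(direction, ra = "rest", ar = "active")
}

#' Duration-dependent transition probability, maximum likelihood
#'
#' Conditional probability of leaving the origin state after exactly s
#' epochs in it, estimated as `Delta*(s) / N*(s)` from the corrected
#' survival counts, for `s = 1..S-1` (S the longest bout).  Durations
#' with `N*(s) = 0` are omitted.
#'
#' @param bouts A `bout_decomposition`.
#' @param direction `"ra"` (rest to active) or `"ar"` (active to rest).
#' @return Object of class `tp_curve` with `s_values`, `probabilities`,
#'   `estimator`, `direction`.
#' @export
tp_ml_duration <- function(bouts, direction = c("ra", "ar")) {
  direction <- match.arg(direction)
  st <- direction_state(direction)
  surv <- survival_counts(bouts, st, corrected = TRUE)
  k <- bout_counts(bouts)
  S <- if (st == "rest") k$S_r else k$S_a
  if (S < 2L) {
    stop("duration curve needs the longest bout to exceed 1 epoch",
         call. = FALSE)
  }
  s <- seq_len(S - 1L)
  # corrected survival table may be shorter than S when the longest bout
  # was the censored terminal one
  N <- ifelse(s <= nrow(surv), surv$N[pmin(s, nrow(surv))], 0)
  delta <- ifelse(s <= nrow(surv), surv$delta[pmin(s, nrow(surv))], 0)
  keep <- N > 0
  structure(
    list(s_values = s[keep], probabilities = (delta / N)[keep],
         estimator = "ML", direction = direction),
    class = "tp_curve"
  )
}

#' Duration-dependent transition probability, heuristic
#'
#' The gap-bridging estimator computed from uncorrected survival counts:
#' for each duration s, the smallest `d >= 1` with `N(s) - N(s+d) > 0` is
#' found and the estimate is `(N(s) - N(s+d)) / (d N(s))`.  When `d = 1`
#' and the terminal state is the destination state this equals the ML
#' curve; `d > 1` points (forced by gaps in the observed bout lengths)
#' are biased but keep the estimate strictly inside (0, 1).
#'
#' @inheritParams tp_ml_duration
#' @return A `tp_curve` with an extra component `d_values`.
#' @export
tp_heuristic_duration <- function(bouts, direction = c("ra", "ar")) {
  direction <- match.arg(direction)
  st <- direction_state(direction)
  surv <- survival_counts(bouts, st, corrected = FALSE)
  S <- nrow(surv)
  if (S < 2L) {
    stop("heuristic curve needs the longest bout to exceed 1 epoch",
         call. = FALSE)
  }
  N_at <- function(s) if (s <= S) surv$N[s] else 0
  s_vals <- seq_len(S - 1L)
  d_vals <- integer(0)
  probs <- numeric(0)
  keep_s <- integer(0)
  for (s in s_vals) {
    Ns <- N_at(s)
    if (Ns == 0) next
    d <- 1L
    while (Ns - N_at(s + d) <= 0) d <- d + 1L
    keep_s <- c(keep_s, s)
    d_vals <- c(d_vals, d)
    probs <- c(probs, (Ns - N_at(s + d)) / (d * Ns))
  }
  if (length(keep_s) == 0L) {
    stop("degenerate curve: no duration admits a positive survival drop",
         call. = FALSE)
  }
  structure(
    list(s_values = keep_s, probabilities = probs, d_values = d_vals,
         estimator = "heuristic", direction = direction),
    class = "tp_curve"
  )
}

#' @export
print.tp_curve <- function(x, ...) {
  cat(sprintf("<tp_curve %s %s> %d durations, range [%.3f, %.3f]\n",
              x$estimator, x$direction, length(x$s_values),
              min(x$probabilities), max(x$probabilities)))
  invisible(x)
}

#' Weighted-mean summary of the duration-dependent ML curve
#'
#' Weighting each duration's ML estimate by its share of surviving bouts
#' collapses the curve to the closed form
#' `(n* - N*(S)) / (T* - N*(S))`, which is what this function returns.
#' With many short bouts (`n*` much larger than `N*(S)`) the summary
#' approaches the order-1 ML estimate, which justifies reporting order-1
#' TPs as summaries of the whole duration profile.
#'
#' Note the closed form replaces the total corrected-bout time
#' `sum_s N*(s)` by `T*`; the two differ by the length of the censored
#' terminal bout minus one, so the closed form and the explicit weighted
#' sum agree exactly only when the origin state does not end the series
#' (or its terminal bout has length 1).  See the methods vignette.
#'
#' @inheritParams tp_ml_duration
#' @return Single probability (the closed form), with the explicit
#'   weighted sum attached as attribute `"weighted_sum"`.
#' @export
tp_weighted_summary <- function(bouts, direction = c("ra", "ar")) {
  direction <- match.arg(direction)
  st <- direction_state(direction)
  k <- bout_counts(bouts)
  n_star <- if (st == "rest") k$n_r_star else k$n_a_star
  T_star <- if (st == "rest") k$T_r_star else k$T_a_star
  S <- if (st == "rest") k$S_r else k$S_a
  surv <- survival_counts(bouts, st, corrected = TRUE)
  N_S <- if (S <= nrow(surv)) surv$N[S] else 0
  denom <- T_star - N_S
  if (denom <= 0) {
    stop("weighted summary undefined: denominator T* - N*(S) is not positive",
         call. = FALSE)
  }
  value <- (n_star - N_S) / denom
  # explicit weighted sum of the ML curve, for cross-checking
  curve <- tp_ml_duration(bouts, direction)
  idx <- curve$s_values
  N_curve <- ifelse(idx <= nrow(surv), surv$N[pmin(idx, nrow(surv))], 0)
  w <- N_curve / sum(N_curve)
  attr(value, "weighted_sum") <- sum(curve$probabilities * w)
  value
}

#' Window-split Bayesian transition probabilities
#'
#' The four headline fragmentation metrics: Bayesian order-1 TPs computed
#' separately within awake and sleep windows from pooled starred tallies,
#' `TP = (sum n* + lambda) / (sum T* + lambda)`.  Always defined; a state
#' absent from a window class yields TP = 1 for transitions out of it.
#'
#' @param states A [state_series].
#' @param windows A [window_map] covering the series exactly.
#' @param lambda Prior pseudo-count in (0, 1].
#' @return Object of class `window_tp` with `tp_ra_w`, `tp_ar_w`,
#'   `tp_ra_s`, `tp_ar_s` and `lambda`.
#' @export
window_tp <- function(states, windows, lambda = 0.5) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0 || lambda > 1) {
    stop("lambda must lie in (0, 1] for window TPs", call. = FALSE)
  }
  sp <- split_by_windows(states, windows)
  w <- sp$awake$counts
  s <- sp$sleep$counts
  structure(
    list(
      tp_ra_w = (w$n_r_star + lambda) / (w$T_r_star + lambda),
      tp_ar_w = (w$n_a_star + lambda) / (w$T_a_star + lambda),
      tp_ra_s = (s$n_r_star + lambda) / (s$T_r_star + lambda),
      tp_ar_s = (s$n_a_star + lambda) / (s$T_a_star + lambda),
      lambda = lambda
    ),
    class = "window_tp"
  )
}

#' @export
print.window_tp <- function(x, ...) {
  cat(sprintf(
    "<window_tp lambda=%g> awake: ra=%.4f ar=%.4f | sleep: ra=%.4f ar=%.4f\n",
    x$lambda, x$tp_ra_w, x$tp_ar_w, x$tp_ra_s, x$tp_ar_s))
  invisible(x)
}
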