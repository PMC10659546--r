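# Seed-deterministic generators for synthetic inputs.
#
# Each generator draws from the statistical model the corresponding
# estimator assumes (AR(1) hourly proportions, two-state Markov chains,
# white/fractal/brown noise), plus a semi-Markov generator for
# duration-dependent structure and a composite 7-day profile for
# end-to-end runs.  The same seed always reproduces the same output.

set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L) {
      stop("seed must be a single integer", call. = FALSE)
    }
    set.seed(as.integer(seed))
  }
}

#' Simulate an AR(1) hourly profile
#'
#' Stationary first-order autoregression around a mean level,
#' `z_p - mu = phi (z_{p-1} - mu) + eps_p` with Gaussian innovations; the
#' working model under which the IV range results hold.  A burn-in of
#' 1000 steps is discarded.  By default values are not clipped to
#' \[0, 1\] so that theoretical properties are undistorted; with
#' `clip = TRUE` the clipped fraction is attached as attribute
#' `"clip_rate"`.
#'
#' @param phi Autocorrelation parameter, `|phi| < 1`.
#' @param P Number of hourly values.
#' @param mu Stationary mean level (default 0.5).
#' @param sigma Innovation standard deviation (default 0.1).
#' @param days Optional day structure to stamp on the profile.
#' @param clip Clip values to \[0, 1\]?
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An [hourly_profile].
#' @export
gen_ar1_hourly <- function(phi, P, mu = 0.5, sigma = 0.1, days = NULL,
                           clip = FALSE, seed = NULL) {
  if (!is.finite(phi) || abs(phi) >= 1) {
    stop("nonstationary specification: |phi| must be < 1", call. = FALSE)
  }
  if (P < 1) stop("P must be positive", call. = FALSE)
  set_seed_if_given(seed)
  burn <- 1000L
  eps <- stats::rnorm(P + burn, sd = sigma)
  u <- stats::filter(eps, phi, method = "recursive")
  z <- mu + as.numeric(u)[(burn + 1L):(burn + P)]
  clip_rate <- 0
  if (clip) {
    clip_rate <- mean(z < 0 | z > 1)
    z <- pmin(pmax(z, 0), 1)
  }
  out <- new_hourly_profile(z, days = days)
  attr(out, "clip_rate") <- clip_rate
  out
}

#' Simulate a two-state Markov chain of rest/activity states
#'
#' Order-1 chain with per-epoch transition probabilities `pi_ra`
#' (rest to active) and `pi_ar` (active to rest), started from its
#' stationary distribution.  Bout lengths are geometric, so all order-1
#' estimators are consistent for the inputs.
#'
#' @param pi_ra,pi_ar Transition probabilities in (0, 1).
#' @param T_len Number of epochs.
#' @param epoch_seconds Epoch duration for the result.
#' @param seed Integer seed.
#' @return A [state_series].
#' @export
gen_markov_states <- function(pi_ra, pi_ar, T_len, epoch_seconds = 60,
                              seed = NULL) {
  if (!is.finite(pi_ra) || pi_ra <= 0 || pi_ra >= 1 ||
      !is.finite(pi_ar) || pi_ar <= 0 || pi_ar >= 1) {
    stop("transition probabilities must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (T_len < 1) stop("T_len must be positive", call. = FALSE)
  set_seed_if_given(seed)
  p_active <- pi_ra / (pi_ra + pi_ar)
  first <- if (stats::runif(1) < p_active) ACTIVE else REST
  # geometric sojourns: draw alternating bout lengths until T is covered
  mean_bout <- 1 / min(pi_ra, pi_ar)
  states <- character(0)
  cur <- first
  total <- 0L
  while (total < T_len) {
    k <- max(2L, ceiling(2 * (T_len - total) / mean_bout) + 8L)
    for (i in seq_len(k)) {
      p <- if (cur == REST) pi_ra else pi_ar
      len <- stats::rgeom(1L, p) + 1L
      states <- c(states, rep(cur, len))
      total <- total + len
      cur <- if (cur == REST) ACTIVE else REST
      if (total >= T_len) break
    }
  }
  state_series(states[seq_len(T_len)], epoch_seconds = epoch_seconds)
}

#' Simulate a semi-Markov rest/activity sequence
#'
#' Alternating states with i.i.d. bout durations drawn from arbitrary
#' per-state distributions (default lognormal), breaking the memoryless
#' property so duration-dependent transition-probability curves are
#' non-flat.
#'
#' @param T_len Number of epochs.
#' @param rest_dur,active_dur Functions taking a count and returning that
#'   many positive durations (rounded up to whole epochs >= 1).
#' @param epoch_seconds Epoch duration.
#' @param seed Integer seed.
#' @return A [state_series].
#' @export
gen_semi_markov_states <- function(T_len,
                                   rest_dur = function(n)
                                     stats::rlnorm(n, log(8), 0.8),
                                   active_dur = function(n)
                                     stats::rlnorm(n, log(15), 1.0),
                                   epoch_seconds = 60,
                                   seed = NULL) {
  if (T_len < 1) stop("T_len must be positive", call. = FALSE)
  set_seed_if_given(seed)
  draw <- function(state, n) {
    d <- ceiling(if (state == REST) rest_dur(n) else active_dur(n))
    if (any(!is.finite(d)) || any(d < 1)) {
      stop("duration distribution produced a non-positive bout length",
           call. = FALSE)
    }
    as.integer(d)
  }
  cur <- if (stats::runif(1) < 0.5) REST else ACTIVE
  states <- character(0)
  total <- 0L
  while (total < T_len) {
    len <- draw(cur, 1L)
    states <- c(states, rep(cur, len))
    total <- total + len
    cur <- if (cur == REST) ACTIVE else REST
  }
  state_series(states[seq_len(T_len)], epoch_seconds = epoch_seconds)
}

# Fractional Gaussian noise by circulant embedding of the autocovariance
# (exact in distribution when the embedding is non-negative definite, as
# it is for fGn).
fgn_sim <- function(T_len, H) {
  n <- T_len
  k <- 0:(n - 1L)
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  m <- 2L * n
  lam <- Re(stats::fft(c(g, 0, rev(g[-1L]))))
  lam <- pmax(lam, 0)
  z <- complex(length.out = m)
  z[1L] <- sqrt(lam[1L]) * stats::rnorm(1)
  z[n + 1L] <- sqrt(lam[n + 1L]) * stats::rnorm(1)
  idx <- 2:n
  u <- stats::rnorm(n - 1L)
  v <- stats::rnorm(n - 1L)
  z[idx] <- sqrt(lam[idx] / 2) * complex(real = u, imaginary = v)
  z[m - idx + 2L] <- Conj(z[idx])
  Re(stats::fft(z))[seq_len(n)] / sqrt(m)
}

#' Simulate noise acceleration series for DFA calibration
#'
#' Three canonical processes: `"white"` (i.i.d. Gaussian, scaling exponent
#' 0.5), `"random_walk"` (cumulative sum of white noise, 1.5), and
#' `"fgn"` (fractional Gaussian noise with Hurst exponent H, scaling
#' exponent H).  Series are shifted so the minimum is zero, which leaves
#' DFA unchanged, and returned in nominal milligravity units.
#'
#' @param kind One of `"white"`, `"random_walk"`, `"fgn"`.
#' @param T_len Number of epochs (>= 16).
#' @param H Hurst exponent in (0, 1), for `kind = "fgn"`.
#' @param sd Innovation standard deviation (default 10 mg).
#' @param epoch_seconds Epoch duration.
#' @param seed Integer seed.
#' @return An [accel_series].
#' @export
gen_noise_accel <- function(kind = c("white", "random_walk", "fgn"),
                            T_len = 10080, H = NULL, sd = 10,
                            epoch_seconds = 60, seed = NULL) {
  kind <- match.arg(kind)
  if (T_len < 16) stop("T_len must be at least 16", call. = FALSE)
  set_seed_if_given(seed)
  x <- switch(kind,
    white = stats::rnorm(T_len, sd = sd),
    random_walk = cumsum(stats::rnorm(T_len, sd = sd)),
    fgn = {
      if (is.null(H) || !is.finite(H) || H <= 0 || H >= 1) {
        stop("fgn requires a Hurst exponent H in (0, 1)", call. = FALSE)
      }
      sd * fgn_sim(T_len, H)
    }
  )
  accel_series(x - min(x), epoch_seconds = epoch_seconds)
}

#' Simulate a realistic seven-day acceleration profile
#'
#' End-to-end fixture: a week of 1-minute epochs starting at waking
#' onset, with each day split into an awake window and a sleep window.
#' Rest/activity states follow a two-state chain whose transition
#' probabilities switch between awake and sleep values at window
#' boundaries; acceleration is then drawn strictly below the threshold
#' for rest epochs and strictly above it for active epochs, so
#' binarizing at the threshold recovers the simulated states exactly.
#'
#' Default transition probabilities (awake: rest to active 0.10, active
#' to rest 0.28; sleep: 0.007 and 0.77) match typical older-adult values,
#' producing consolidated sleep and fragmented daytime activity.
#'
#' @param days Number of days (default 7).
#' @param awake_hours Awake window length per day in hours (default 16).
#' @param tp_awake,tp_sleep Named vectors `c(ra = ..., ar = ...)` of
#'   per-epoch transition probabilities in each window class.
#' @param threshold_mg Acceleration threshold separating the rest and
#'   active draw ranges (default 40).
#' @param epoch_seconds Epoch duration (default 60).
#' @param sleep_active_rate Set to 0 to force sleep windows to contain no
#'   activity at all (exercising the missing-state rule); 1 leaves the
#'   chain untouched (default).
#' @param seed Integer seed.
#' @return List with `accel` ([accel_series]), `windows` ([window_map]),
#'   and the underlying `states` ([state_series]).
#' @export
gen_weekly_profile <- function(days = 7, awake_hours = 16,
                               tp_awake = c(ra = 0.10, ar = 0.28),
                               tp_sleep = c(ra = 0.007, ar = 0.77),
                               threshold_mg = 40, epoch_seconds = 60,
                               sleep_active_rate = 1, seed = NULL) {
  if (awake_hours <= 0 || awake_hours >= 24) {
    stop("awake_hours must lie strictly between 0 and 24", call. = FALSE)
  }
  set_seed_if_given(seed)
  eph <- as.integer(3600 / epoch_seconds)
  awake_len <- as.integer(awake_hours * eph)
  day_len <- 24L * eph
  sleep_len <- day_len - awake_len
  T_len <- days * day_len

  w_start <- integer(0); w_end <- integer(0); w_lab <- character(0)
  for (d in seq_len(days) - 1L) {
    w_start <- c(w_start, d * day_len, d * day_len + awake_len)
    w_end <- c(w_end, d * day_len + awake_len, (d + 1L) * day_len)
    w_lab <- c(w_lab, "awake", "sleep")
  }
  windows <- window_map(w_start, w_end, w_lab)

  is_sleep <- rep(rep(c(FALSE, TRUE), times = c(awake_len, sleep_len)), days)
  states <- character(T_len)
  cur <- ACTIVE  # the record starts at waking onset
  for (t in seq_len(T_len)) {
    tp <- if (is_sleep[t]) tp_sleep else tp_awake
    p_switch <- if (cur == REST) tp[["ra"]] else tp[["ar"]]
    if (t > 1L && stats::runif(1) < p_switch) {
      cur <- if (cur == REST) ACTIVE else REST
    }
    if (is_sleep[t] && cur == ACTIVE && sleep_active_rate <= 0) {
      cur <- REST
    }
    states[t] <- cur
  }

  active <- states == ACTIVE
  x <- numeric(T_len)
  # rest strictly at or below threshold, activity strictly above it
  x[!active] <- stats::runif(sum(!active), 0, 0.9 * threshold_mg)
  x[active] <- threshold_mg * 1.05 +
    stats::rgamma(sum(active), shape = 2, scale = threshold_mg)
  list(
    accel = accel_series(x, epoch_seconds = epoch_seconds),
    windows = windows,
    states = state_series(states, epoch_seconds = epoch_seconds,
                          threshold_mg = threshold_mg)
  )
}
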