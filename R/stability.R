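# Inter-daily stability, intradaily variability and the AR(1) diagnostic.
#
# Both metrics operate on the hourly proportion-active series z, never on
# raw acceleration: the proved ranges (IS in [0,1]; IV tending to [0,2]
# for a stationary AR(1) with non-negative autocorrelation) hold for z
# only.

# Resolve an hourly_profile or plain numeric vector to its values.
profile_values <- function(profile) {
  if (inherits(profile, "hourly_profile")) profile$values
  else as.numeric(profile)
}

stop_if_degenerate <- function(z) {
  if (stats::var(z) == 0) {
    stop("profile is constant: variance is zero and the metric is 0/0",
         call. = FALSE)
  }
}

#' Inter-daily stability (IS)
#'
#' Ratio of the variance of the mean 24-hour profile (hour means across
#' days) to the total variance of the hourly series: a signal-to-noise
#' measure of how reproducible the daily rest-activity pattern is.
#' IS is 1 when all days are identical and near 1/D for structureless
#' noise over D days.
#'
#' @param profile An [hourly_profile] with a day structure, or a numeric
#'   vector (then `days` is required).
#' @param days Number of complete days D (taken from the profile when
#'   available).
#' @param hours_per_day Hours per day H.
#' @return IS in \[0, 1\].
#' @export
inter_daily_stability <- function(profile, days = NULL, hours_per_day = 24) {
  z <- profile_values(profile)
  if (inherits(profile, "hourly_profile")) {
    if (is.null(days)) days <- profile$days
    hours_per_day <- profile$hours_per_day
  }
  if (is.null(days)) {
    stop("IS requires a day structure: supply `days` or a profile with one",
         call. = FALSE)
  }
  if (days < 2) {
    stop("IS requires at least 2 complete days", call. = FALSE)
  }
  P <- length(z)
  H <- hours_per_day
  if (P != days * H) {
    stop(sprintf("profile length %d != days (%d) x hours_per_day (%d)",
                 P, days, H), call. = FALSE)
  }
  stop_if_degenerate(z)
  zbar <- mean(z)
  # hour h mean over days: z laid out day-major (day 1 hours 1..H, ...)
  zmat <- matrix(z, nrow = H, ncol = days)
  hour_means <- rowMeans(zmat)
  (P * sum((hour_means - zbar)^2)) / (H * sum((z - zbar)^2))
}

#' Intradaily variability (IV)
#'
#' Normalised mean squared successive difference of the hourly series,
#' taken across the whole observation period including day boundaries.
#' Values near 0 indicate a smooth rhythm; values near 2 indicate
#' hour-to-hour noise; values above 2 can occur for short series or
#' negative lag-1 autocorrelation (ultradian rhythms) and are reported
#' as-is.
#'
#' @param profile An [hourly_profile] or numeric vector of length P >= 2.
#' @return IV >= 0.
#' @export
intradaily_variability <- function(profile) {
  z <- profile_values(profile)
  P <- length(z)
  if (P < 2) stop("IV requires at least 2 hourly values", call. = FALSE)
  stop_if_degenerate(z)
  (P * sum(diff(z)^2)) / ((P - 1) * sum((z - mean(z))^2))
}

#' Lag-1 autocorrelation of the hourly profile
#'
#' Sample lag-1 autocorrelation (Yule-Walker order 1) of z, used as a
#' diagnostic under the AR(1) working model: negative estimates signal
#' ultradian (shorter-than-daily) rhythmicity, the regime in which IV may
#' exceed 2.
#'
#' @param profile An [hourly_profile] or numeric vector of length P >= 3.
#' @return List with `phi_hat` and logical `ultradian_flag`
#'   (`phi_hat < 0`).
#' @export
estimate_phi <- function(profile) {
  z <- profile_values(profile)
  P <- length(z)
  if (P < 3) stop("phi estimation requires at least 3 values", call. = FALSE)
  stop_if_degenerate(z)
  zc <- z - mean(z)
  phi <- sum(zc[-1L] * zc[-P]) / sum(zc^2)
  list(phi_hat = phi, ultradian_flag = phi < 0)
}

#' IS, IV and the AR(1) diagnostic in one call
#'
#' @param profile An [hourly_profile] with a day structure.
#' @return Object of class `stability_result`: `IS`, `IV`, `phi_hat`,
#'   `ultradian_flag`.
#' @export
stability_metrics <- function(profile) {
  phi <- estimate_phi(profile)
  structure(
    list(
      IS = inter_daily_stability(profile),
      IV = intradaily_variability(profile),
      phi_hat = phi$phi_hat,
      ultradian_flag = phi$ultradian_flag
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> IS=%.3f IV=%.3f phi_hat=%.3f%s\n",
              x$IS, x$IV, x$phi_hat,
              if (x$ultradian_flag) " [ultradian]" else ""))
  invisible(x)
}
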