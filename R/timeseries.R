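# Time-series containers and bout machinery.
#
# Three views of one individual's recording are distinguished throughout the
# package: the acceleration series x (one value per epoch, milligravity),
# the binary rest/activity state series y, and the hourly proportion-active
# series z.  Keeping them as distinct classes prevents a thresholded series
# from being silently re-thresholded downstream.

REST <- "rest"
ACTIVE <- "active"

#' Epoch-level acceleration series
#'
#' Container for a per-epoch acceleration record (typically ENMO in
#' milligravity at 60-second epochs).  Values must be finite and
#' non-negative; the epoch duration is carried along so hourly aggregation
#' and window conversion can be validated.
#'
#' @param values Numeric vector, one acceleration value per epoch (mg).
#' @param epoch_seconds Duration of one epoch in seconds (default 60).
#' @param start Optional POSIXct timestamp of the first epoch.
#' @return An object of class `accel_series`.
#' @examples
#' x <- accel_series(c(50, 10, 41, 40))
#' binarize(x, threshold_mg = 40)
#' @export
accel_series <- function(values, epoch_seconds = 60, start = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("acceleration series must contain at least one epoch", call. = FALSE)
  }
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite acceleration value at epoch %d", bad[1L]),
         call. = FALSE)
  }
  neg <- which(values < 0)
  if (length(neg) > 0L) {
    stop(sprintf("negative acceleration value at epoch %d", neg[1L]),
         call. = FALSE)
  }
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L ||
      epoch_seconds <= 0) {
    stop("epoch_seconds must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, epoch_seconds = epoch_seconds, start = start),
    class = "accel_series"
  )
}

#' @export
length.accel_series <- function(x) length(x$values)

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> T=%d epochs of %gs, range [%.1f, %.1f] mg\n",
              length(x$values), x$epoch_seconds,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Rest/activity state series
#'
#' Binary per-epoch state sequence over the two-letter alphabet
#' rest/active.  Inputs may use the shorthand `"r"`/`"a"`.
#'
#' @param states Character vector of `"rest"`/`"active"` (or `"r"`/`"a"`).
#' @param epoch_seconds Duration of one epoch in seconds.
#' @param threshold_mg Optional provenance: the acceleration threshold that
#'   produced the states.
#' @return An object of class `state_series`.
#' @examples
#' y <- state_series(c("a", "a", "r", "r", "a"))
#' extract_bouts(y)
#' @export
state_series <- function(states, epoch_seconds = 60, threshold_mg = NULL) {
  states <- as.character(states)
  if (length(states) < 1L) {
    stop("state series must contain at least one epoch", call. = FALSE)
  }
  states[states == "r"] <- REST
  states[states == "a"] <- ACTIVE
  bad <- which(!(states %in% c(REST, ACTIVE)))
  if (length(bad) > 0L) {
    stop(sprintf("invalid state '%s' at epoch %d (must be rest/active)",
                 states[bad[1L]], bad[1L]), call. = FALSE)
  }
  structure(
    list(states = states, epoch_seconds = epoch_seconds,
         threshold_mg = threshold_mg),
    class = "state_series"
  )
}

#' @export
length.state_series <- function(x) length(x$states)

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("<state_series> T=%d epochs of %gs, %.1f%% active\n",
              length(x$states), x$epoch_seconds,
              100 * mean(x$states == ACTIVE)))
  invisible(x)
}

#' Hourly proportion-active profile
#'
#' The hourly series z: for each hour block, the fraction of epochs spent
#' in the active state.  This is the input to inter-daily stability and
#' intradaily variability.  `days` may be `NULL` for profiles without a
#' day structure (IV and the AR(1) diagnostic do not need one; IS does).
#'
#' @param values Numeric vector of proportions in \[0, 1\].
#' @param days Number of complete days D, or `NULL` if unstructured.
#' @param hours_per_day Hours per day H (default 24).
#' @return An object of class `hourly_profile`.
#' @export
hourly_profile <- function(values, days = NULL, hours_per_day = 24) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("hourly profile values must be finite", call. = FALSE)
  }
  if (any(values < 0 | values > 1)) {
    stop("hourly proportions must lie in [0, 1]", call. = FALSE)
  }
  new_hourly_profile(values, days, hours_per_day)
}

# Internal constructor: skips the [0, 1] range check so that simulated
# AR(1) profiles (unclipped by design for the theorem suite) can share the
# class.  The public constructor enforces the range.
new_hourly_profile <- function(values, days = NULL, hours_per_day = 24) {
  if (!is.null(days)) {
    if (length(values) != days * hours_per_day) {
      stop(sprintf("profile length %d != days (%d) x hours_per_day (%d)",
                   length(values), days, hours_per_day), call. = FALSE)
    }
  }
  structure(
    list(values = values, days = days, hours_per_day = hours_per_day),
    class = "hourly_profile"
  )
}

#' @export
length.hourly_profile <- function(x) length(x$values)

#' @export
print.hourly_profile <- function(x, ...) {
  cat(sprintf("<hourly_profile> P=%d hours%s, mean %.3f\n",
              length(x$values),
              if (is.null(x$days)) "" else sprintf(" (D=%d, H=%d)",
                                                   x$days, x$hours_per_day),
              mean(x$values)))
  invisible(x)
}

#' Awake/sleep window map
#'
#' Ordered, non-overlapping half-open intervals `[start, end)` in epoch
#' indices (0-based), each labelled awake or sleep.  Labels of contiguous
#' intervals must alternate.  Coverage of the whole series is checked at
#' split time, not at construction.
#'
#' @param start,end Integer epoch indices; each interval is `[start, end)`.
#' @param label Character vector over `{"awake", "sleep"}`.
#' @return An object of class `window_map`.
#' @examples
#' window_map(c(0, 960), c(960, 1440), c("awake", "sleep"))
#' @export
window_map <- function(start, end, label) {
  start <- as.integer(start)
  end <- as.integer(end)
  label <- as.character(label)
  n <- length(start)
  if (length(end) != n || length(label) != n || n < 1L) {
    stop("start, end and label must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(!(label %in% c("awake", "sleep")))) {
    stop("window labels must be 'awake' or 'sleep'", call. = FALSE)
  }
  if (any(end <= start) || any(start < 0L)) {
    stop("each window must satisfy 0 <= start < end", call. = FALSE)
  }
  o <- order(start)
  start <- start[o]; end <- end[o]; label <- label[o]
  if (n > 1L) {
    if (any(start[-1L] < end[-n])) {
      stop("windows overlap", call. = FALSE)
    }
    contiguous <- start[-1L] == end[-n]
    same <- label[-1L] == label[-n]
    if (any(contiguous & same)) {
      stop("contiguous windows must alternate awake/sleep labels",
           call. = FALSE)
    }
  }
  structure(
    list(start = start, end = end, label = label),
    class = "window_map"
  )
}

#' @export
print.window_map <- function(x, ...) {
  cat(sprintf("<window_map> %d intervals over epochs [%d, %d)\n",
              length(x$start), min(x$start), max(x$end)))
  invisible(x)
}

#' Binarize acceleration into rest/activity states
#'
#' An epoch is active iff its acceleration strictly exceeds the threshold
#' (epochs exactly at the threshold are rest).  The conventional threshold
#' for wrist ENMO is 40 mg.
#'
#' @param accel An [accel_series] (or numeric vector of mg values).
#' @param threshold_mg Positive acceleration threshold in milligravity.
#' @return A [state_series] of the same length.
#' @examples
#' binarize(accel_series(c(50, 10, 41, 40)), 40)
#' @export
binarize <- function(accel, threshold_mg = 40) {
  if (!inherits(accel, "accel_series")) accel <- accel_series(accel)
  if (!is.numeric(threshold_mg) || length(threshold_mg) != 1L ||
      !is.finite(threshold_mg) || threshold_mg <= 0) {
    stop("threshold_mg must be a single positive number", call. = FALSE)
  }
  state_series(
    ifelse(accel$values > threshold_mg, ACTIVE, REST),
    epoch_seconds = accel$epoch_seconds,
    threshold_mg = threshold_mg
  )
}

#' Aggregate states to hourly proportions
#'
#' Collapses the state series into consecutive non-overlapping blocks of
#' `epochs_per_hour` epochs aligned to the series start, each summarised by
#' its fraction of active epochs.  A series length not divisible by the
#' block size is an error, never a silent truncation.
#'
#' @param states A [state_series].
#' @param epochs_per_hour Number of epochs forming one hour block
#'   (default inferred from `epoch_seconds`).
#' @param days Optional number of complete days to record on the profile;
#'   inferred when the number of blocks is divisible by `hours_per_day`.
#' @param hours_per_day Hours per day (default 24).
#' @return An [hourly_profile] with `P = T / epochs_per_hour` values.
#' @export
hourly_proportions <- function(states,
                               epochs_per_hour = NULL,
                               days = NULL,
                               hours_per_day = 24) {
  stopifnot(inherits(states, "state_series"))
  if (is.null(epochs_per_hour)) {
    epochs_per_hour <- 3600 / states$epoch_seconds
  }
  if (epochs_per_hour < 1 || epochs_per_hour != round(epochs_per_hour)) {
    stop("epochs_per_hour must be a positive integer", call. = FALSE)
  }
  epochs_per_hour <- as.integer(epochs_per_hour)
  T_len <- length(states$states)
  if (T_len %% epochs_per_hour != 0L) {
    stop(sprintf(
      "series length %d is not divisible by epochs_per_hour %d",
      T_len, epochs_per_hour), call. = FALSE)
  }
  active <- states$states == ACTIVE
  P <- T_len %/% epochs_per_hour
  z <- colMeans(matrix(active, nrow = epochs_per_hour, ncol = P))
  if (is.null(days) && P %% hours_per_day == 0L) {
    days <- P %/% hours_per_day
  }
  new_hourly_profile(z, days = days, hours_per_day = hours_per_day)
}

#' Decompose a state series into rest and activity bouts
#'
#' Run-length encodes the series into maximal bouts of each state and
#' records the terminal state.  The terminal-state ("starred") corrections
#' subtract one bout and one epoch from the tallies of the state that ends
#' the series, because that bout's ending is unobserved.
#'
#' @param states A [state_series].
#' @return An object of class `bout_decomposition` with components
#'   `lengths` and `values` (the run-length encoding, in order),
#'   `rest_bouts`, `activity_bouts`, `last_state`, and `T`.
#'   Use [bout_counts()] for the derived tallies.
#' @examples
#' y <- state_series(strsplit("aaarrararrarr", "")[[1]][1:13])
#' extract_bouts(y)
#' @export
extract_bouts <- function(states) {
  stopifnot(inherits(states, "state_series"))
  r <- rle(states$states)
  structure(
    list(
      lengths = r$lengths,
      values = r$values,
      rest_bouts = r$lengths[r$values == REST],
      activity_bouts = r$lengths[r$values == ACTIVE],
      last_state = states$states[length(states$states)],
      T = length(states$states)
    ),
    class = "bout_decomposition"
  )
}

#' Bout tallies with terminal-state corrections
#'
#' @param bouts A `bout_decomposition`.
#' @return Named list with `n_r`, `n_a` (bout counts), `T_r`, `T_a`
#'   (total epochs per state), `S_r`, `S_a` (longest bout; 0 if the state
#'   is absent), and the starred corrections `n_r_star`, `n_a_star`,
#'   `T_r_star`, `T_a_star`.
#' @export
bout_counts <- function(bouts) {
  stopifnot(inherits(bouts, "bout_decomposition"))
  r <- bouts$rest_bouts
  a <- bouts$activity_bouts
  last_r <- bouts$last_state == REST
  list(
    n_r = length(r),
    n_a = length(a),
    T_r = sum(r),
    T_a = sum(a),
    S_r = if (length(r)) max(r) else 0L,
    S_a = if (length(a)) max(a) else 0L,
    n_r_star = length(r) - as.integer(last_r),
    n_a_star = length(a) - as.integer(!last_r),
    T_r_star = sum(r) - as.integer(last_r),
    T_a_star = sum(a) - as.integer(!last_r)
  )
}

#' @export
print.bout_decomposition <- function(x, ...) {
  k <- bout_counts(x)
  cat(sprintf(
    "<bout_decomposition> T=%d; rest: n=%d (n*=%d) T=%d (T*=%d); active: n=%d (n*=%d) T=%d (T*=%d); last=%s\n",
    x$T, k$n_r, k$n_r_star, k$T_r, k$T_r_star,
    k$n_a, k$n_a_star, k$T_a, k$T_a_star, x$last_state))
  invisible(x)
}

#' Expand a bout decomposition back to a state series
#'
#' Inverse of [extract_bouts()]; useful for round-trip checks.
#'
#' @param bouts A `bout_decomposition`.
#' @param epoch_seconds Epoch duration to stamp on the result.
#' @return A [state_series].
#' @export
expand_bouts <- function(bouts, epoch_seconds = 60) {
  stopifnot(inherits(bouts, "bout_decomposition"))
  state_series(rep(bouts$values, bouts$lengths),
               epoch_seconds = epoch_seconds)
}

#' Bout-duration survival counts
#'
#' For one state, N(s) counts the bouts of duration at least s and
#' Delta(s) = N(s) - N(s+1) counts the bouts of duration exactly s.  The
#' corrected variant drops the final bout of the series when that state
#' ends it (its true duration is censored).
#'
#' @param bouts A `bout_decomposition`.
#' @param state `"rest"` or `"active"`.
#' @param corrected Apply the terminal-bout correction?
#' @return A data frame with columns `s` (1..S), `N` and `delta`.
#' @examples
#' y <- state_series(c("a","a","a","r","r","a","r","a","a","a","r","r","a","r","r"))
#' survival_counts(extract_bouts(y), "rest")
#' survival_counts(extract_bouts(y), "rest", corrected = TRUE)
#' @export
survival_counts <- function(bouts, state = c("rest", "active"),
                            corrected = FALSE) {
  stopifnot(inherits(bouts, "bout_decomposition"))
  state <- match.arg(state)
  lens <- if (state == REST) bouts$rest_bouts else bouts$activity_bouts
  if (corrected && bouts$last_state == state) {
    lens <- lens[-length(lens)]  # drop the terminal (censored) bout
  }
  if (length(lens) == 0L) {
    stop(sprintf("no %s%s bouts available for survival counts",
                 if (corrected) "corrected " else "", state), call. = FALSE)
  }
  S <- max(lens)
  s <- seq_len(S)
  N <- vapply(s, function(k) sum(lens >= k), numeric(1))
  delta <- N - c(N[-1L], 0)
  data.frame(s = s, N = N, delta = delta)
}

#' Split a state series by awake/sleep windows
#'
#' Each window interval is treated as an independent sequence: bouts never
#' span a window boundary, and every window contributes its own
#' terminal-bout correction.  Starred tallies per label are sums over that
#' label's windows.
#'
#' @param states A [state_series].
#' @param windows A [window_map] covering `[0, T)` exactly.
#' @return A list of class `window_split` with one entry per label
#'   (`awake`, `sleep`), each containing `bouts` (list of per-window
#'   `bout_decomposition`s) and `counts` (summed starred tallies as in
#'   [bout_counts()]).
#' @export
split_by_windows <- function(states, windows) {
  stopifnot(inherits(states, "state_series"), inherits(windows, "window_map"))
  T_len <- length(states$states)
  if (windows$start[1L] != 0L || windows$end[length(windows$end)] != T_len ||
      (length(windows$start) > 1L &&
       any(windows$start[-1L] != windows$end[-length(windows$end)]))) {
    stop(sprintf(
      "windows must cover [0, %d) exactly with no gaps or overlaps", T_len),
      call. = FALSE)
  }
  out <- list()
  for (lab in c("awake", "sleep")) {
    idx <- which(windows$label == lab)
    blist <- lapply(idx, function(i) {
      seg <- states$states[(windows$start[i] + 1L):windows$end[i]]
      extract_bouts(state_series(seg, states$epoch_seconds))
    })
    counts <- list(n_r_star = 0L, n_a_star = 0L, T_r_star = 0L,
                   T_a_star = 0L, n_r = 0L, n_a = 0L, T_r = 0L, T_a = 0L)
    for (b in blist) {
      k <- bout_counts(b)
      for (f in names(counts)) counts[[f]] <- counts[[f]] + k[[f]]
    }
    out[[lab]] <- list(bouts = blist, counts = counts)
  }
  structure(out, class = "window_split")
}
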