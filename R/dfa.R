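# Detrended fluctuation analysis and the activity balance index.
#
# The scaling exponent alpha is the log-log slope of the RMS fluctuation
# of the integrated, per-box-detrended acceleration signal against box
# size: 0.5 for white noise, 1 for fractal (pink) noise, 1.5 for a random
# walk.  The activity balance index maps alpha onto (0, 1], peaking at the
# fractal point alpha = 1.

#' Integrate an acceleration series
#'
#' Cumulative sum of the mean-centred signal, `c_t = sum_{i<=t}(x_i - xbar)`;
#' the profile DFA operates on.  The last value is 0 up to rounding.
#'
#' @param accel An [accel_series] or numeric vector.
#' @return Numeric vector `c` of the same length, with attribute
#'   `"constant"` set to `TRUE` when the input had zero variance (the
#'   scaling exponent is then undefined downstream).
#' @export
integrate_profile <- function(accel) {
  x <- if (inherits(accel, "accel_series")) accel$values else as.numeric(accel)
  if (length(x) < 16L) {
    stop("DFA requires at least 16 epochs so the box grid [4, T/4] exists",
         call. = FALSE)
  }
  cc <- cumsum(x - mean(x))
  attr(cc, "constant") <- stats::var(x) == 0
  cc
}

#' Log-spaced box-size grid
#'
#' Box sizes for the fluctuation function: `count` log-spaced values
#' rounded to unique integers within the recommended range
#' `[4, floor(T/4)]`.
#'
#' @param T_len Series length.
#' @param count Requested grid size (>= 2); duplicates after rounding are
#'   dropped, so the result may be shorter.
#' @return Strictly increasing integer vector.
#' @export
box_grid <- function(T_len, count = 30) {
  if (T_len < 16L) stop("T must be at least 16", call. = FALSE)
  if (count < 2L) stop("grid size must be at least 2", call. = FALSE)
  n_max <- floor(T_len / 4)
  unique(round(exp(seq(log(4), log(n_max), length.out = count))))
}

#' Root-mean-square fluctuation at one box size
#'
#' Splits the integrated series into `B = floor(T/n)` non-overlapping
#' boxes of n epochs, removes a least-squares polynomial trend of order
#' `poly_order` from each box, and returns the RMS of the residuals over
#' the first `B * n` points (any remainder shorter than one box is
#' discarded).
#'
#' @param c_series Integrated series from [integrate_profile()].
#' @param n Box size, `4 <= n <= T/4`.
#' @param poly_order Detrending polynomial order `l` (default 1, classic
#'   DFA-1); requires `n >= l + 2` so the fit is determined.
#' @return F(n) >= 0.
#' @export
fluctuation <- function(c_series, n, poly_order = 1) {
  T_len <- length(c_series)
  n <- as.integer(n)
  if (n < 4L || n > T_len / 4) {
    stop(sprintf("box size %d outside [4, T/4] = [4, %d]", n,
                 floor(T_len / 4)), call. = FALSE)
  }
  if (n < poly_order + 2L) {
    stop(sprintf("box size %d too small for polynomial order %d", n,
                 poly_order), call. = FALSE)
  }
  B <- T_len %/% n
  used <- B * n
  cmat <- matrix(c_series[seq_len(used)], nrow = n, ncol = B)
  # one design matrix serves all boxes: residuals of a polynomial fit are
  # invariant to the affine shift between global and within-box time
  tt <- seq_len(n)
  X <- stats::poly(tt, degree = poly_order, raw = TRUE)
  X <- cbind(1, X)
  res <- qr.resid(qr(X), cmat)
  sqrt(sum(res^2) / used)
}

#' Scaling exponent from the fluctuation grid
#'
#' Ordinary least-squares fit of `log F(n) = mu + alpha log n`; the slope
#' is the self-similarity estimate.  Grid points with `F(n) = 0`
#' (perfectly detrended boxes) are dropped with a warning.
#'
#' @param box_sizes Integer vector of box sizes.
#' @param fluctuations F(n) values of the same length.
#' @return List with `alpha_hat`, `intercept`, `r_squared`, `n_used`.
#' @export
estimate_alpha <- function(box_sizes, fluctuations) {
  if (length(box_sizes) != length(fluctuations)) {
    stop("box_sizes and fluctuations must have equal length", call. = FALSE)
  }
  keep <- fluctuations > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d grid point(s) with F(n) = 0 from the fit",
                    sum(!keep)))
  }
  if (sum(keep) < 2L) {
    stop("scaling exponent undefined: fewer than 2 positive F(n) values",
         call. = FALSE)
  }
  lx <- log(box_sizes[keep])
  ly <- log(fluctuations[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  list(alpha_hat = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r_squared = r2,
       n_used = sum(keep))
}

#' Detrended fluctuation analysis
#'
#' Full pipeline: integrate the acceleration series, evaluate F(n) on a
#' log-spaced box grid in `[4, T/4]`, and estimate the scaling exponent
#' by log-log OLS.
#'
#' @param accel An [accel_series] or numeric vector (length >= 16).
#' @param grid_size Number of requested box sizes (default 30).
#' @param poly_order Detrending order (default 1).
#' @return Object of class `dfa_result`: `box_sizes`, `fluctuations`,
#'   `alpha_hat`, `fit_intercept`, `r_squared`, `poly_order`.
#' @examples
#' set.seed(1)
#' d <- dfa(gen_noise_accel("white", T_len = 2048, seed = 1))
#' d$alpha_hat  # close to 0.5
#' @export
dfa <- function(accel, grid_size = 30, poly_order = 1) {
  cc <- integrate_profile(accel)
  if (isTRUE(attr(cc, "constant"))) {
    stop("constant input: all fluctuations are zero and alpha is undefined",
         call. = FALSE)
  }
  grid <- box_grid(length(cc), grid_size)
  grid <- grid[grid >= poly_order + 2L]
  f <- vapply(grid, function(n) fluctuation(cc, n, poly_order), numeric(1))
  est <- estimate_alpha(grid, f)
  structure(
    list(box_sizes = grid, fluctuations = f,
         alpha_hat = est$alpha_hat, fit_intercept = est$intercept,
         r_squared = est$r_squared, poly_order = poly_order),
    class = "dfa_result"
  )
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf(
    "<dfa_result> alpha_hat=%.3f (R2=%.3f) over %d box sizes [%d, %d], order %d\n",
    x$alpha_hat, x$r_squared, length(x$box_sizes),
    min(x$box_sizes), max(x$box_sizes), x$poly_order))
  invisible(x)
}

#' Activity balance index (ABI)
#'
#' Monotone transform of the distance of the scaling exponent from the
#' fractal point: `ABI = exp(-|alpha - 1| * e^2)`.  Equals 1 exactly at
#' alpha = 1 and falls to `exp(-e^2) ~ 0.0006` at the extremes alpha = 0
#' and alpha = 2, penalising departures in both directions symmetrically.
#'
#' @param alpha_hat Estimated scaling exponent; values outside (0, 2)
#'   are accepted with a warning.
#' @param rate Scale constant multiplying `|alpha - 1|` (default `exp(2)`).
#' @return ABI in (0, 1].
#' @examples
#' abi(1)    # 1
#' abi(0)    # ~0.0006
#' abi(1.5)  # ~0.0248
#' @export
abi <- function(alpha_hat, rate = exp(2)) {
  if (!is.numeric(alpha_hat) || any(!is.finite(alpha_hat))) {
    stop("alpha_hat must be finite", call. = FALSE)
  }
  if (any(alpha_hat <= 0 | alpha_hat >= 2)) {
    warning("alpha_hat outside the theoretical range (0, 2)")
  }
  exp(-abs(alpha_hat - 1) * rate)
}
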