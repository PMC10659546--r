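# File interfaces and the per-subject metric panel.

#' Read an epoch-level acceleration CSV
#'
#' Expects a header with columns `timestamp` (ISO-8601) and `enmo_mg`
#' (acceleration in milligravity), one row per epoch.  Epoch duration is
#' inferred from the timestamp spacing and must be constant; gaps and
#' duplicate timestamps are errors that name the offending timestamps.
#'
#' @param path Path to the CSV file.
#' @return An [accel_series] with `start` set to the first timestamp.
#' @export
read_epoch_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty epoch file: ", path, call. = FALSE)
  if (!all(c("timestamp", "enmo_mg") %in% names(df))) {
    stop("epoch CSV must have columns 'timestamp' and 'enmo_mg'",
         call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (any(is.na(ts))) {
    stop(sprintf("unparseable timestamp at row %d", which(is.na(ts))[1L]),
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df$enmo_mg))
  if (any(is.na(vals))) {
    stop(sprintf("non-numeric enmo_mg at row %d", which(is.na(vals))[1L]),
         call. = FALSE)
  }
  if (nrow(df) == 1L) {
    return(accel_series(vals, epoch_seconds = 60, start = ts[1L]))
  }
  d <- as.numeric(difftime(ts[-1L], ts[-length(ts)], units = "secs"))
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("duplicate or non-increasing timestamp at %s",
                 format(ts[i + 1L])), call. = FALSE)
  }
  step <- min(d)
  gaps <- which(d != step)
  if (length(gaps) > 0L) {
    spans <- paste(vapply(utils::head(gaps, 5L), function(i) {
      sprintf("%s -> %s", format(ts[i]), format(ts[i + 1L]))
    }, character(1)), collapse = "; ")
    stop(sprintf("irregular spacing / missing epochs at: %s%s", spans,
                 if (length(gaps) > 5L) " ..." else ""), call. = FALSE)
  }
  accel_series(vals, epoch_seconds = step, start = ts[1L])
}

#' Read an awake/sleep window CSV
#'
#' Expects columns `start`, `end` and `label` (`awake`/`sleep`).  Bounds
#' may be integer epoch indices (half-open, 0-based) or ISO-8601
#' timestamps, which are converted to epoch indices relative to the
#' series start.
#'
#' @param path Path to the CSV file.
#' @param accel The [accel_series] the windows refer to (needed to
#'   convert timestamp bounds).
#' @return A [window_map].
#' @export
read_window_csv <- function(path, accel = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty window file: ", path, call. = FALSE)
  if (!all(c("start", "end", "label") %in% names(df))) {
    stop("window CSV must have columns 'start', 'end' and 'label'",
         call. = FALSE)
  }
  to_epoch <- function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!any(is.na(num))) return(as.integer(num))
    if (is.null(accel) || is.null(accel$start)) {
      stop("timestamp window bounds require an accel series with a start time",
           call. = FALSE)
    }
    ts <- as.POSIXct(v, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS"))
    if (any(is.na(ts))) stop("unparseable window timestamp", call. = FALSE)
    idx <- as.numeric(difftime(ts, accel$start, units = "secs")) /
      accel$epoch_seconds
    if (any(idx != round(idx))) {
      stop("window bound does not fall on an epoch boundary", call. = FALSE)
    }
    as.integer(round(idx))
  }
  window_map(to_epoch(df$start), to_epoch(df$end), df$label)
}

metric_or_reason <- function(expr) {
  tryCatch(list(value = expr, reason = NA_character_),
           error = function(e) list(value = NA_real_,
                                    reason = conditionMessage(e)))
}

#' Compute the full fragmentation metric panel for one subject
#'
#' Pipeline: binarize the acceleration series, aggregate to hourly
#' proportions, and compute IS, IV, the AR(1) diagnostic, the four
#' window-split Bayesian transition probabilities, the DFA scaling
#' exponent and the activity balance index.  Metrics whose preconditions
#' fail (e.g. a constant profile) are reported as `NA` with a reason code
#' rather than aborting the record.
#'
#' @param accel An [accel_series].
#' @param windows A [window_map] covering the series; `NULL` treats the
#'   whole series as one awake window (sleep TPs are then undefined).
#' @param subject_id Identifier carried into the record.
#' @param threshold_mg Rest/activity threshold (default 40 mg).
#' @param lambda Bayesian pseudo-count in (0, 1] (default 0.5).
#' @param dfa_grid Number of DFA box sizes (default 30).
#' @param dfa_order DFA detrending order (default 1).
#' @return Object of class `metrics_record`: the nine metrics, a
#'   `reasons` list for any undefined ones, and `provenance`.
#' @export
compute_all <- function(accel, windows = NULL, subject_id = "subject",
                        threshold_mg = 40, lambda = 0.5,
                        dfa_grid = 30, dfa_order = 1) {
  stopifnot(inherits(accel, "accel_series"))
  T_len <- length(accel)
  states <- binarize(accel, threshold_mg)
  if (is.null(windows)) {
    windows <- window_map(0L, T_len, "awake")
  }
  eph <- 3600 / accel$epoch_seconds
  prof <- metric_or_reason(hourly_proportions(states))
  stab <- if (is.na(prof$reason)) {
    list(
      IS = metric_or_reason(inter_daily_stability(prof$value)),
      IV = metric_or_reason(intradaily_variability(prof$value)),
      phi = metric_or_reason(estimate_phi(prof$value)$phi_hat)
    )
  } else {
    list(IS = prof, IV = prof, phi = prof)
  }
  tp <- metric_or_reason(window_tp(states, windows, lambda))
  dfa_res <- metric_or_reason(dfa(accel, grid_size = dfa_grid,
                                  poly_order = dfa_order))
  alpha <- if (is.na(dfa_res$reason)) dfa_res$value$alpha_hat else NA_real_
  abi_val <- if (is.finite(alpha)) abi(alpha) else NA_real_

  vals <- list(
    subject_id = subject_id,
    IS = stab$IS$value,
    IV = stab$IV$value,
    phi_hat = stab$phi$value,
    TP_ra_w = if (is.na(tp$reason)) tp$value$tp_ra_w else NA_real_,
    TP_ar_w = if (is.na(tp$reason)) tp$value$tp_ar_w else NA_real_,
    TP_ra_s = if (is.na(tp$reason)) tp$value$tp_ra_s else NA_real_,
    TP_ar_s = if (is.na(tp$reason)) tp$value$tp_ar_s else NA_real_,
    alpha_hat = alpha,
    ABI = abi_val
  )
  reasons <- list(
    IS = stab$IS$reason, IV = stab$IV$reason, phi_hat = stab$phi$reason,
    TP = tp$reason, alpha_hat = dfa_res$reason
  )
  reasons <- reasons[!is.na(reasons)]
  structure(
    c(vals, list(
      reasons = reasons,
      provenance = list(
        threshold_mg = threshold_mg, lambda = lambda,
        epoch_seconds = accel$epoch_seconds,
        dfa_grid = dfa_grid, dfa_order = dfa_order,
        epochs = T_len,
        version = as.character(utils::packageVersion("fragmetrics"))
      )
    )),
    class = "metrics_record"
  )
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics_record> %s\n", x$subject_id))
  for (m in c("IS", "IV", "phi_hat", "TP_ra_w", "TP_ar_w", "TP_ra_s",
              "TP_ar_s", "alpha_hat", "ABI")) {
    cat(sprintf("  %-9s %s\n", m,
                if (is.na(x[[m]])) "NA" else sprintf("%.4f", x[[m]])))
  }
  if (length(x$reasons)) {
    cat("  undefined:", paste(names(x$reasons), collapse = ", "), "\n")
  }
  invisible(x)
}

metric_fields <- c("IS", "IV", "phi_hat", "TP_ra_w", "TP_ar_w",
                   "TP_ra_s", "TP_ar_s", "alpha_hat", "ABI")

#' Write metric records to JSON or CSV
#'
#' JSON output is a lossless array of records including provenance and
#' reason codes; CSV output has one row per subject with provenance
#' columns flattened.
#'
#' @param records A `metrics_record` or list of them.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(records, "metrics_record")) records <- list(records)
  if (format == "json") {
    payload <- lapply(records, function(r) {
      r <- unclass(r)
      r
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    rows <- lapply(records, function(r) {
      pv <- r$provenance
      base <- lapply(c(list(subject_id = r$subject_id),
                       r[metric_fields]), identity)
      c(base, stats::setNames(pv, paste0("prov_", names(pv))))
    })
    df <- do.call(rbind, lapply(rows, function(x)
      as.data.frame(x, stringsAsFactors = FALSE)))
    if (is.null(df)) {
      df <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(metric_fields) + 1L),
        c("subject_id", metric_fields)))
    }
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write an epoch/window CSV pair for a simulated subject
#'
#' Serialises the output of [gen_weekly_profile()] in the formats
#' [read_epoch_csv()] and [read_window_csv()] accept, for fixture
#' generation and CLI round trips.
#'
#' @param sim List from [gen_weekly_profile()].
#' @param epoch_path,window_path Output CSV paths.
#' @param start Timestamp of the first epoch.
#' @return Invisibly, the two paths.
#' @export
write_simulation_csv <- function(sim, epoch_path, window_path,
                                 start = as.POSIXct("2020-01-06 07:00:00",
                                                    tz = "UTC")) {
  T_len <- length(sim$accel)
  ts <- start + (seq_len(T_len) - 1L) * sim$accel$epoch_seconds
  utils::write.csv(
    data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
               enmo_mg = sim$accel$values),
    epoch_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(start = sim$windows$start, end = sim$windows$end,
               label = sim$windows$label),
    window_path, row.names = FALSE, quote = FALSE)
  invisible(c(epoch_path, window_path))
}
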