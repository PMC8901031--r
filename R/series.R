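#' Build a canonical CGM glucose series
#'
#' A `cgm_series` is a tibble with a `time` column (POSIXct, treated as naive
#' local wall-clock; no time-zone arithmetic is performed) and a `glucose`
#' column (interstitial glucose, mg/dL), sorted by time with duplicate
#' timestamps removed, plus attributes recording the nominal sampling
#' interval and the device the data came from. Every metric and plot in the
#' package consumes this shape; any plain data frame with `time` and
#' `glucose` columns is accepted by those functions and canonicalized on the
#' fly.
#'
#' Canonicalization sorts rows by timestamp and, for exact-duplicate
#' timestamps, keeps the first occurrence in the input order. Glucose values
#' must lie inside the hard sanity bounds \[10, 1000\] mg/dL; values outside
#' raise a validation error listing the offending rows. No interpolation or
#' imputation is ever performed: gaps remain gaps.
#'
#' @param data A data frame with a timestamp column and a glucose column.
#' @param time_col,glucose_col Names of the timestamp and glucose columns.
#' @param interval_min Nominal sampling cadence in minutes (e.g. 5 for
#'   Dexcom-style, 15 for Libre-style sensors). If `NULL`, inferred as the
#'   median spacing between consecutive readings.
#' @param device Free-text provenance label stored on the series.
#' @return A `cgm_series` tibble with columns `time` and `glucose` and
#'   attributes `interval_min`, `device` and `parse_log`.
#' @examples
#' df <- data.frame(
#'   time = as.POSIXct("2023-03-01 08:00", tz = "UTC") + 300 * (0:5),
#'   glucose = c(100, 110, 120, 118, 112, 105)
#' )
#' as_cgm_series(df, interval_min = 5)
#' @export
as_cgm_series <- function(data, time_col = "time", glucose_col = "glucose",
                          interval_min = NULL, device = "generic") {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "cgm_parameter_error")
  }
  missing_cols <- setdiff(c(time_col, glucose_col), names(data))
  if (length(missing_cols) > 0) {
    abort(
      sprintf(
        "Column(s) %s not found. Available columns: %s.",
        paste0("'", missing_cols, "'", collapse = ", "),
        paste0("'", names(data), "'", collapse = ", ")
      ),
      class = "cgm_format_error"
    )
  }
  time <- data[[time_col]]
  if (!inherits(time, "POSIXct")) {
    time <- parse_cgm_time(as.character(time))
  }
  glucose <- data[[glucose_col]]
  if (!is.numeric(glucose)) {
    glucose <- suppressWarnings(as.numeric(as.character(glucose)))
  }
  keep <- !is.na(time) & !is.na(glucose)
  n_unparseable <- sum(!keep)
  time <- time[keep]
  glucose <- glucose[keep]
  if (length(time) == 0) {
    abort(
      "No parseable readings: need a timestamp column and a numeric glucose column (mg/dL).",
      class = "cgm_format_error"
    )
  }
  bad <- which(glucose < glucose_bounds[["lower"]] |
                 glucose > glucose_bounds[["upper"]])
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Glucose outside sanity bounds [%g, %g] mg/dL in %d row(s): %s.",
        glucose_bounds[["lower"]], glucose_bounds[["upper"]], length(bad),
        paste(sprintf("%s = %g", format(time[bad]), glucose[bad]),
              collapse = "; ")
      ),
      class = "cgm_validation_error"
    )
  }
  ord <- order(time)
  time <- time[ord]
  glucose <- glucose[ord]
  dup <- duplicated(time)
  n_dup <- sum(dup)
  time <- time[!dup]
  glucose <- glucose[!dup]
  if (is.null(interval_min)) {
    interval_min <- if (length(time) > 1) {
      stats::median(as.numeric(diff(time), units = "mins"))
    } else {
      5
    }
  }
  if (!is.numeric(interval_min) || length(interval_min) != 1 ||
      !is.finite(interval_min) || interval_min <= 0) {
    abort("`interval_min` must be a single positive number.",
          class = "cgm_parameter_error")
  }
  new_cgm_series(
    time, glucose, interval_min = interval_min, device = device,
    parse_log = list(rows_read = nrow(data), dropped_nonnumeric = n_unparseable,
                     duplicates_removed = n_dup)
  )
}

new_cgm_series <- function(time, glucose, interval_min, device,
                           parse_log = NULL) {
  out <- tibble(time = time, glucose = as.numeric(glucose))
  class(out) <- c("cgm_series", class(out))
  attr(out, "interval_min") <- as.numeric(interval_min)
  attr(out, "device") <- device
  attr(out, "parse_log") <- parse_log
  out
}

# Parse device timestamps: ISO-8601 and the US-style formats used by Dexcom
# and Libre exports. Naive wall-clock; stored as UTC so no DST arithmetic
# ever applies.
parse_cgm_time <- function(x) {
  suppressWarnings(lubridate::parse_date_time(
    x,
    orders = c("Ymd HMS", "Ymd HM", "mdY HMS", "mdY HM", "mdy HM p",
               "mdy HMS p"),
    tz = "UTC", quiet = TRUE
  ))
}

# Light canonicalization for plain data frames handed straight to a metric:
# verify columns, coerce, sort. Fast no-op on an already-canonical series.
prep_series <- function(data) {
  if (inherits(data, "cgm_series") && !is.unsorted(data$time)) {
    return(data)
  }
  interval <- attr(data, "interval_min", exact = TRUE)
  as_cgm_series(data, interval_min = interval,
                device = attr(data, "device", exact = TRUE) %||% "generic")
}

series_interval <- function(data) {
  iv <- attr(data, "interval_min", exact = TRUE)
  if (!is.null(iv)) {
    return(iv)
  }
  if (nrow(data) > 1) {
    stats::median(as.numeric(diff(data$time), units = "mins"))
  } else {
    5
  }
}

#' @export
print.cgm_series <- function(x, ...) {
  cat(sprintf(
    "# CGM series: %d readings, device '%s', nominal interval %g min\n",
    nrow(x), attr(x, "device") %||% "unknown", series_interval(x)
  ))
  NextMethod()
}

#' Partition a glucose series into calendar days
#'
#' Groups readings by calendar date (day boundary at local midnight). Days
#' with fewer than two readings are flagged `thin`; intraday dispersion
#' metrics and ADRR skip thin days because a within-day SD is undefined
#' there.
#'
#' @param data A `cgm_series` or data frame with `time` and `glucose`.
#' @return A tibble with one row per calendar day: `day` (Date), `n`
#'   (readings), `start`, `end` (first/last timestamp) and `thin` (fewer
#'   than 2 readings).
#' @examples
#' s <- simulate_cgm(sim_profile(n_days = 2, seed = 1))
#' cgm_days(s)
#' @export
cgm_days <- function(data) {
  data <- prep_series(data)
  dplyr::summarise(
    dplyr::group_by(
      tibble(day = lubridate::as_date(data$time), time = data$time),
      .data$day
    ),
    n = dplyr::n(),
    start = min(.data$time),
    end = max(.data$time),
    .groups = "drop"
  ) |>
    dplyr::arrange(.data$day) |>
    dplyr::mutate(thin = .data$n < 2)
}

# Per-reading day keys, used internally by intraday metrics.
day_keys <- function(data) lubridate::as_date(data$time)

#' Locate sampling gaps in a glucose series
#'
#' Flags maximal intervals where the spacing between consecutive readings
#' exceeds `tolerance_factor` times the nominal sampling interval. Gaps are
#' reported for completeness accounting only; the package never fills them
#' with fabricated readings.
#'
#' @inheritParams cgm_days
#' @param tolerance_factor Multiple of the nominal interval beyond which a
#'   spacing counts as a gap. Must be >= 1.
#' @return A tibble with columns `start`, `end` (the readings flanking the
#'   gap) and `duration_min`. Zero rows when the series is regular.
#' @examples
#' s <- simulate_cgm(sim_profile(n_days = 1, gaps = list(c(6, 90)), seed = 1))
#' find_gaps(s)
#' @export
find_gaps <- function(data, tolerance_factor = 1.5) {
  if (!is.numeric(tolerance_factor) || length(tolerance_factor) != 1 ||
      tolerance_factor < 1) {
    abort("`tolerance_factor` must be a single number >= 1.",
          class = "cgm_parameter_error")
  }
  data <- prep_series(data)
  if (nrow(data) < 2) {
    return(tibble(time = data$time[0], end = data$time[0],
                  duration_min = numeric(0)) |>
             dplyr::rename(start = "time"))
  }
  spacing <- as.numeric(diff(data$time), units = "mins")
  idx <- which(spacing > tolerance_factor * series_interval(data))
  tibble(
    start = data$time[idx],
    end = data$time[idx + 1],
    duration_min = spacing[idx]
  )
}

#' One-row summary of a glucose series
#'
#' @param x A `cgm_series`.
#' @param ... Unused.
#' @return A one-row tibble: reading count, day count, time span, nominal
#'   interval, device label and data completeness (observed readings over
#'   the readings a gap-free record at the nominal cadence would hold).
#' @method glance cgm_series
#' @export
glance.cgm_series <- function(x, ...) {
  x <- prep_series(x)
  span_min <- as.numeric(difftime(max(x$time), min(x$time), units = "mins"))
  expected <- span_min / series_interval(x) + 1
  tibble(
    n = nrow(x),
    n_days = length(unique(day_keys(x))),
    start = min(x$time),
    end = max(x$time),
    interval_min = series_interval(x),
    device = attr(x, "device") %||% "unknown",
    completeness = min(1, nrow(x) / expected)
  )
}
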