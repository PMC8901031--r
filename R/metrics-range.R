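#' Glucose band at k standard deviations from the mean
#'
#' The dispersion band `(mean - k*SD, mean + k*SD)` that parameterizes
#' time-in-range, MGE and MGN and the band visualization.
#'
#' @inheritParams interday_mean
#' @param k SD multiplier (default 1).
#' @return A one-row tibble with `lower` and `upper` (mg/dL).
#' @examples
#' glucose_band(simulate_cgm(sim_profile(seed = 1)), k = 1)
#' @export
glucose_band <- function(data, k = 1) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 0) {
    abort("`k` must be a single non-negative number.",
          class = "cgm_parameter_error")
  }
  s <- interday_sd(data)
  if (is_undefined_metric(s)) {
    abort("Glucose band needs at least 2 readings (SD undefined).",
          class = "cgm_parameter_error")
  }
  m <- interday_mean(data)
  tibble(lower = m - k * s, upper = m + k * s)
}

band_mask <- function(data, k) {
  band <- glucose_band(data, k)
  g <- prep_series(data)$glucose
  g >= band$lower & g <= band$upper
}

resolve_sr <- function(data, sr) {
  sr <- sr %||% series_interval(data)
  if (!is.numeric(sr) || length(sr) != 1 || !is.finite(sr) || sr <= 0) {
    abort("`sr` must be a single positive number of minutes.",
          class = "cgm_parameter_error")
  }
  sr
}

#' Time and percent in/outside the mean +/- k SD band
#'
#' Each reading represents `sr` minutes of wear time (defaulting to the
#' series' nominal sampling interval). `time_in_range()` counts readings
#' inside the closed band `[mean - k*SD, mean + k*SD]`;
#' `time_outside_range()` counts strict excursions; the percent forms are
#' their shares of total observed time, so `percent_in_range() +
#' percent_outside_range() = 100` and `time_in_range() +
#' time_outside_range()` equals total observed duration.
#'
#' @inheritParams glucose_band
#' @param sr Minutes represented by one reading; defaults to the nominal
#'   sampling interval.
#' @return Minutes (`time_*`) or percent (`percent_*`).
#' @examples
#' s <- simulate_cgm(sim_profile(seed = 1))
#' time_in_range(s)
#' percent_outside_range(s)
#' @export
time_in_range <- function(data, k = 1, sr = NULL) {
  data <- prep_series(data)
  sum(band_mask(data, k)) * resolve_sr(data, sr)
}

#' @rdname time_in_range
#' @export
time_outside_range <- function(data, k = 1, sr = NULL) {
  data <- prep_series(data)
  sum(!band_mask(data, k)) * resolve_sr(data, sr)
}

#' @rdname time_in_range
#' @export
percent_in_range <- function(data, k = 1, sr = NULL) {
  data <- prep_series(data)
  100 * mean(band_mask(data, k))
}

#' @rdname time_in_range
#' @export
percent_outside_range <- function(data, k = 1, sr = NULL) {
  100 - percent_in_range(data, k, sr)
}

#' Time below, within and above clinical thresholds
#'
#' Splits observed wear time by the standard (or personalized) clinical
#' thresholds for hypoglycemia and hyperglycemia: strictly below `hypo`,
#' inside the closed range `[hypo, hyper]`, strictly above `hyper`. The
#' three durations always sum to the total observed duration.
#'
#' @inheritParams time_in_range
#' @param hypo Hypoglycemia threshold, mg/dL (default 70).
#' @param hyper Hyperglycemia threshold, mg/dL (default 180).
#' @return A one-row tibble: `minutes_below`, `minutes_in`, `minutes_above`.
#' @examples
#' clinical_range_times(simulate_cgm(sim_profile(seed = 1)))
#' @export
clinical_range_times <- function(data, hypo = 70, hyper = 180, sr = NULL) {
  if (!is.numeric(hypo) || !is.numeric(hyper) || hypo >= hyper) {
    abort("`hypo` must be strictly less than `hyper` (mg/dL).",
          class = "cgm_parameter_error")
  }
  data <- prep_series(data)
  sr <- resolve_sr(data, sr)
  g <- data$glucose
  tibble(
    minutes_below = sum(g < hypo) * sr,
    minutes_in = sum(g >= hypo & g <= hyper) * sr,
    minutes_above = sum(g > hyper) * sr
  )
}

#' Mean glycemic excursion level (MGE) and mean of normal glucose (MGN)
#'
#' MGE is the mean glucose of readings strictly outside the mean +/- k SD
#' band (the excursion readings); MGN is the mean of readings inside the
#' closed band. Companion metrics to the band-based time in range.
#'
#' @inheritParams glucose_band
#' @return mg/dL, or an [undefined_metric()] when no reading falls on the
#'   relevant side of the band.
#' @examples
#' s <- simulate_cgm(sim_profile(seed = 1))
#' mge(s)
#' mgn(s)
#' @export
mge <- function(data, k = 1) {
  data <- prep_series(data)
  outside <- data$glucose[!band_mask(data, k)]
  if (length(outside) == 0) {
    return(undefined_metric(
      sprintf("no readings outside the mean +/- %g SD band", k)
    ))
  }
  mean(outside)
}

#' @rdname mge
#' @export
mgn <- function(data, k = 1) {
  data <- prep_series(data)
  inside <- data$glucose[band_mask(data, k)]
  if (length(inside) == 0) {
    return(undefined_metric(
      sprintf("no readings inside the mean +/- %g SD band", k)
    ))
  }
  mean(inside)
}
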