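#' Interday summary metrics
#'
#' Statistics pooled over every reading in the record, regardless of day:
#' mean and median glucose, the sample (n-1) standard deviation, and the
#' coefficient of variation. "Interday" follows the field's convention of
#' contrasting whole-record dispersion with per-day ("intraday")
#' dispersion — see [intraday_sd()].
#'
#' @param data A `cgm_series` or data frame with `time` and `glucose`
#'   columns (mg/dL).
#' @return `interday_mean()`, `interday_median()` — mg/dL.
#'   `interday_sd()` — mg/dL, or an [undefined_metric()] with fewer than 2
#'   readings. `interday_cv()` — percent, 100 * SD / mean.
#' @examples
#' s <- simulate_cgm(sim_profile(seed = 42))
#' interday_mean(s)
#' interday_cv(s)
#' @export
interday_mean <- function(data) {
  mean(prep_series(data)$glucose)
}

#' @rdname interday_mean
#' @export
interday_median <- function(data) {
  stats::median(prep_series(data)$glucose)
}

#' @rdname interday_mean
#' @export
interday_sd <- function(data) {
  g <- prep_series(data)$glucose
  if (length(g) < 2) {
    return(undefined_metric("fewer than 2 readings"))
  }
  stats::sd(g)
}

#' @rdname interday_mean
#' @export
interday_cv <- function(data) {
  s <- interday_sd(data)
  if (is_undefined_metric(s)) {
    return(s)
  }
  100 * s / interday_mean(data)
}

#' Pooled distribution summary of a glucose series
#'
#' Mean, median, minimum, maximum and quartiles of all readings pooled
#' across days. Quartiles use linear interpolation between order statistics
#' (the default quantile definition in R).
#'
#' @inheritParams interday_mean
#' @return A one-row tibble: `mean`, `median`, `min`, `max`, `q1`, `q3`
#'   (all mg/dL).
#' @examples
#' summary_stats(simulate_cgm(sim_profile(seed = 1)))
#' @export
summary_stats <- function(data) {
  g <- prep_series(data)$glucose
  q <- stats::quantile(g, c(0.25, 0.75), names = FALSE, type = 7)
  tibble(
    mean = mean(g), median = stats::median(g),
    min = min(g), max = max(g), q1 = q[1], q3 = q[2]
  )
}

#' J-index
#'
#' Composite of central tendency and dispersion (Wojcicki's formulation for
#' glucose in mg/dL): `0.001 * (mean + SD)^2`.
#'
#' @inheritParams interday_mean
#' @return Unitless value; undefined with fewer than 2 readings.
#' @examples
#' j_index(simulate_cgm(sim_profile(seed = 1)))
#' @export
j_index <- function(data) {
  s <- interday_sd(data)
  if (is_undefined_metric(s)) {
    return(s)
  }
  0.001 * (interday_mean(data) + s)^2
}

#' Glucose management indicator (GMI)
#'
#' Linear map of mean glucose to an estimated hemoglobin A1c percentage:
#' `GMI(%) = 3.31 + 0.02392 * mean glucose (mg/dL)`.
#'
#' @inheritParams interday_mean
#' @return Percent A1c.
#' @examples
#' gmi(simulate_cgm(sim_profile(seed = 1)))
#' @export
gmi <- function(data) {
  gmi_constants$intercept + gmi_constants$slope * interday_mean(data)
}

#' Estimated A1c (eA1c)
#'
#' ADAG-study linear map of mean glucose to estimated A1c:
#' `eA1c(%) = (mean glucose + 46.7) / 28.7`.
#'
#' @inheritParams interday_mean
#' @return Percent A1c.
#' @examples
#' ea1c(simulate_cgm(sim_profile(seed = 1)))
#' @export
ea1c <- function(data) {
  (interday_mean(data) + ea1c_constants$offset) / ea1c_constants$scale
}
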