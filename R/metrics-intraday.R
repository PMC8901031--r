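intraday_stat <- function(data, stat) {
  data <- prep_series(data)
  per_day <- split(data$glucose, day_keys(data))
  per_day <- per_day[vapply(per_day, length, 1L) >= 2]  # skip thin days
  if (length(per_day) == 0) {
    out <- tibble(mean = NA_real_, median = NA_real_, sd = NA_real_)
    attr(out, "cgm_reason") <- "no day has 2 or more readings"
    attr(out, "n_days") <- 0L
    return(out)
  }
  values <- vapply(per_day, stat, numeric(1))
  out <- tibble(
    mean = mean(values),
    median = stats::median(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_
  )
  if (length(values) < 2) {
    attr(out, "cgm_reason") <- "across-day SD needs 2 or more days"
  }
  attr(out, "n_days") <- length(values)
  out
}

#' Intraday (within-day) dispersion
#'
#' Computes the sample SD (respectively CV) of glucose within each calendar
#' day, then aggregates across days: the mean, median and SD of the per-day
#' values. Days with fewer than two readings are skipped (a within-day SD
#' is undefined there). With a single usable day the across-day `sd` is
#' reported as `NA` with the reason in the `cgm_reason` attribute.
#'
#' @inheritParams interday_mean
#' @return A one-row tibble with columns `mean`, `median`, `sd` (mg/dL for
#'   `intraday_sd()`, percent for `intraday_cv()`); attribute `n_days`
#'   records how many days contributed.
#' @examples
#' s <- simulate_cgm(sim_profile(n_days = 7, seed = 1))
#' intraday_sd(s)
#' intraday_cv(s)
#' @export
intraday_sd <- function(data) {
  intraday_stat(data, stats::sd)
}

#' @rdname intraday_sd
#' @export
intraday_cv <- function(data) {
  intraday_stat(data, function(g) 100 * stats::sd(g) / mean(g))
}
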