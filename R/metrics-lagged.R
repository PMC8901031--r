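# Pair each reading with the reading closest to (t - lag), accepting
# candidates within +/- tolerance minutes; on an exact distance tie the
# earlier candidate wins. Returns integer indices (NA where no pair).
# Timestamp pairing (rather than index shifting) keeps MODD/CONGA honest on
# irregular records: gaps simply reduce the pair count.
lag_pairs <- function(time_min, lag_min, tolerance_min) {
  target <- time_min - lag_min
  lo <- findInterval(target, time_min)  # largest j with time[j] <= target
  n <- length(time_min)
  pick <- rep(NA_integer_, n)
  cand_lo <- pmax(lo, 1L)
  cand_hi <- pmin(lo + 1L, n)
  d_lo <- abs(time_min[cand_lo] - target)
  d_hi <- abs(time_min[cand_hi] - target)
  use_lo <- lo >= 1L & d_lo <= tolerance_min & (d_lo <= d_hi | lo + 1L > n)
  use_hi <- !use_lo & lo + 1L <= n & d_hi <= tolerance_min
  pick[use_lo] <- cand_lo[use_lo]
  pick[use_hi] <- cand_hi[use_hi]
  pick
}

lagged_differences <- function(data, lag_hours, pair_tolerance_min) {
  data <- prep_series(data)
  tol <- pair_tolerance_min %||% (series_interval(data) / 2)
  if (!is.numeric(tol) || length(tol) != 1 || tol < 0) {
    abort("`pair_tolerance_min` must be a single non-negative number.",
          class = "cgm_parameter_error")
  }
  t_min <- as.numeric(data$time) / 60
  pair <- lag_pairs(t_min, lag_hours * 60, tol)
  ok <- !is.na(pair)
  list(
    diff = data$glucose[ok] - data$glucose[pair[ok]],
    n_pairs = sum(ok), tolerance_min = tol
  )
}

#' Mean of daily differences (MODD)
#'
#' For each reading at time `t`, finds the reading 24 hours earlier (the
#' nearest candidate within `pair_tolerance_min`; exact ties resolve to the
#' earlier reading) and averages the absolute glucose differences. Measures
#' day-to-day reproducibility of the glucose profile: 0 for a perfectly
#' 24-hour-periodic trace.
#'
#' @inheritParams interday_mean
#' @param pair_tolerance_min Maximal timestamp mismatch, in minutes, when
#'   pairing readings 24 h apart. Defaults to half the nominal sampling
#'   interval.
#' @return mg/dL, with the pair count in attribute `n_pairs`; an
#'   [undefined_metric()] when the record yields no 24-h pairs.
#' @examples
#' modd(simulate_cgm(sim_profile(n_days = 7, seed = 1)))
#' @export
modd <- function(data, pair_tolerance_min = NULL) {
  d <- lagged_differences(data, 24, pair_tolerance_min)
  if (d$n_pairs == 0) {
    return(undefined_metric("no readings pair across a 24-h lag"))
  }
  out <- mean(abs(d$diff))
  attr(out, "n_pairs") <- d$n_pairs
  out
}

#' Continuous overall net glycemic action, CONGA(n)
#'
#' The sample standard deviation of the differences between each reading
#' and the reading `n_hours` earlier, using the same timestamp-pairing rule
#' as [modd()]. The package default lag is 24 hours.
#'
#' @inheritParams modd
#' @param n_hours Lag in hours (default 24).
#' @return mg/dL, with the pair count in attribute `n_pairs`; an
#'   [undefined_metric()] with fewer than 2 pairs.
#' @examples
#' conga(simulate_cgm(sim_profile(n_days = 7, seed = 1)), n_hours = 24)
#' @export
conga <- function(data, n_hours = 24, pair_tolerance_min = NULL) {
  if (!is.numeric(n_hours) || length(n_hours) != 1 || n_hours <= 0) {
    abort("`n_hours` must be a single positive number.",
          class = "cgm_parameter_error")
  }
  d <- lagged_differences(data, n_hours, pair_tolerance_min)
  if (d$n_pairs < 2) {
    return(undefined_metric(
      sprintf("fewer than 2 readings pair across a %g-h lag", n_hours)
    ))
  }
  out <- stats::sd(d$diff)
  attr(out, "n_pairs") <- d$n_pairs
  out
}
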