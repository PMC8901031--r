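#' Kovatchev blood-glucose risk transform
#'
#' Maps each reading through the symmetrizing risk function
#' `f(G) = 1.509 * ((ln G)^1.084 - 5.381)` (G in mg/dL), which places
#' euglycemia near zero and stretches the hypoglycemic range so that low
#' and high excursions carry comparable risk. The per-reading risk is
#' `10 * f^2`, assigned to the low side (`rl`) when `f < 0` and to the high
#' side (`rh`) when `f > 0`; exactly one of `rl`, `rh` is nonzero per
#' reading.
#'
#' @inheritParams interday_mean
#' @return A tibble with one row per reading: `time`, `glucose`, `f`, `rl`,
#'   `rh`.
#' @examples
#' risk_transform(simulate_cgm(sim_profile(seed = 1)))
#' @export
risk_transform <- function(data) {
  data <- prep_series(data)
  f <- risk_constants$scale *
    (log(data$glucose)^risk_constants$power - risk_constants$offset)
  risk <- 10 * f^2
  tibble(
    time = data$time, glucose = data$glucose, f = f,
    rl = ifelse(f < 0, risk, 0),
    rh = ifelse(f > 0, risk, 0)
  )
}

#' Low and high blood-glucose indices (LBGI, HBGI)
#'
#' LBGI is the mean of the low-side risk `rl` over all readings, HBGI the
#' mean of the high-side risk `rh` (see [risk_transform()]). Both are
#' non-negative and unitless; LBGI is exactly 0 on a trace that never dips
#' into the hypoglycemic side of the transform (all readings at or above
#' ~113 mg/dL), and symmetrically for HBGI.
#'
#' @inheritParams interday_mean
#' @return Unitless non-negative value.
#' @examples
#' s <- simulate_cgm(sim_profile(seed = 1))
#' lbgi(s)
#' hbgi(s)
#' @export
lbgi <- function(data) {
  mean(risk_transform(data)$rl)
}

#' @rdname lbgi
#' @export
hbgi <- function(data) {
  mean(risk_transform(data)$rh)
}

#' Average daily risk range (ADRR)
#'
#' For each calendar day with at least two readings, take the day's maximal
#' low-side risk and maximal high-side risk (see [risk_transform()]); ADRR
#' is the mean over days of their sum. Captures how far into risky
#' territory a typical day swings, in both directions.
#'
#' @inheritParams interday_mean
#' @return Unitless non-negative value, or an [undefined_metric()] when no
#'   day has two or more readings.
#' @examples
#' adrr(simulate_cgm(sim_profile(n_days = 7, seed = 1)))
#' @export
adrr <- function(data) {
  data <- prep_series(data)
  rt <- risk_transform(data)
  rt$day <- day_keys(data)
  daily <- dplyr::summarise(
    dplyr::group_by(rt, .data$day),
    n = dplyr::n(),
    risk_range = max(.data$rl) + max(.data$rh),
    .groups = "drop"
  )
  daily <- daily[daily$n >= 2, , drop = FALSE]
  if (nrow(daily) == 0) {
    return(undefined_metric("no day has 2 or more readings"))
  }
  mean(daily$risk_range)
}
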