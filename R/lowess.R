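#' LOWESS smoothing of a glucose series
#'
#' Locally weighted scatterplot smoothing (tricube weights, optional
#' robustness iterations) of glucose against time, evaluated at every
#' observation time. This is the smoother behind [plot_smoothed()], exposed
#' standalone so the smoothed trace can be analyzed or exported.
#'
#' @inheritParams interday_mean
#' @param fraction Smoothing span: the fraction of readings contributing to
#'   each local fit, in (0, 1]. Default 0.1.
#' @param iterations Robustness iterations downweighting outliers (>= 0).
#'   Default 2.
#' @return A tibble aligned to the input: `time`, `glucose` (raw) and
#'   `smoothed` (mg/dL).
#' @examples
#' s <- simulate_cgm(sim_profile(n_days = 2, seed = 1))
#' lowess_smooth(s, fraction = 0.1)
#' @export
lowess_smooth <- function(data, fraction = 0.1, iterations = 2) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single number in (0, 1].",
          class = "cgm_parameter_error")
  }
  if (!is.numeric(iterations) || length(iterations) != 1 || iterations < 0) {
    abort("`iterations` must be a single non-negative integer.",
          class = "cgm_parameter_error")
  }
  data <- prep_series(data)
  if (nrow(data) < 3) {
    abort("LOWESS smoothing needs at least 3 readings.",
          class = "cgm_parameter_error")
  }
  x <- as.numeric(data$time)
  fit <- stats::lowess(x, data$glucose, f = fraction, iter = iterations,
                       delta = 0)
  tibble(time = data$time, glucose = data$glucose, smoothed = fit$y)
}
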