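# Default theme for the figure family: red mean/hyperglycemia accents,
# pink dispersion band, yellow hypoglycemia. A config list, not hard-coded
# aesthetics, so house styles can be swapped in.
cgm_palette <- list(
  trace = "grey30", mean = "red", band = "pink",
  hyper = "red", hypo = "yellow", smooth = "blue"
)

#' Longitudinal CGM visualizations
#'
#' Four ggplot2 views of a glucose series:
#' * `plot_band()`: the trace with the whole-record mean (red line) and the
#'   mean +/- k SD dispersion band (pink ribbon).
#' * `plot_thresholds()`: the trace with hyperglycemia (> `hyper`, red) and
#'   hypoglycemia (< `hypo`, yellow) regions shaded.
#' * `plot_smoothed()`: the trace overlaid with its [lowess_smooth()]
#'   curve.
#' * `plot_by_day()`: one trace per calendar day against time of day
#'   (00:00-24:00), for eyeballing day-to-day reproducibility.
#'
#' Every plot's computed data layer (the exact coordinates drawn) is
#' attached as attribute `"cgm_data"`, so rendering can be verified
#' headlessly without image comparison; the layers are pure functions of
#' the series and parameters.
#'
#' @inheritParams interday_mean
#' @param k SD multiplier for the dispersion band.
#' @param hypo,hyper Clinical thresholds in mg/dL (defaults 70 and 180).
#' @param fraction,iterations LOWESS span and robustness passes, as in
#'   [lowess_smooth()].
#' @param days Optional subset of calendar days (anything coercible by
#'   [as.Date()]); all days when `NULL`.
#' @param palette Named list of colors; see the package default for keys.
#' @return A ggplot object with attribute `cgm_data` (a list of the tibbles
#'   behind each layer).
#' @examples
#' s <- simulate_cgm(sim_profile(n_days = 3, seed = 7))
#' plot_band(s)
#' plot_by_day(s)
#' @export
plot_band <- function(data, k = 1, palette = cgm_palette) {
  data <- prep_series(data)
  band <- glucose_band(data, k)
  m <- interday_mean(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$glucose)) +
    ggplot2::annotate("rect", xmin = min(data$time), xmax = max(data$time),
                      ymin = band$lower, ymax = band$upper,
                      fill = palette$band, alpha = 0.6) +
    ggplot2::geom_line(color = palette$trace) +
    ggplot2::geom_hline(yintercept = m, color = palette$mean) +
    cgm_plot_labs("Glucose with mean and dispersion band",
                  sprintf("mean %.1f mg/dL, band = mean +/- %g SD", m, k))
  attr(p, "cgm_data") <- list(series = as_tibble(data), band = band,
                              mean = m)
  p
}

#' @rdname plot_band
#' @export
plot_thresholds <- function(data, hypo = 70, hyper = 180,
                            palette = cgm_palette) {
  if (!is.numeric(hypo) || !is.numeric(hyper) || hypo >= hyper) {
    abort("`hypo` must be strictly less than `hyper` (mg/dL).",
          class = "cgm_parameter_error")
  }
  data <- prep_series(data)
  ylim_top <- max(max(data$glucose), hyper) + 10
  ylim_bot <- min(min(data$glucose), hypo) - 10
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$glucose)) +
    ggplot2::annotate("rect", xmin = min(data$time), xmax = max(data$time),
                      ymin = hyper, ymax = ylim_top,
                      fill = palette$hyper, alpha = 0.25) +
    ggplot2::annotate("rect", xmin = min(data$time), xmax = max(data$time),
                      ymin = ylim_bot, ymax = hypo,
                      fill = palette$hypo, alpha = 0.35) +
    ggplot2::geom_line(color = palette$trace) +
    ggplot2::geom_hline(yintercept = c(hypo, hyper), linetype = "dashed",
                        color = c(palette$hypo, palette$hyper)) +
    cgm_plot_labs("Glucose with clinical thresholds",
                  sprintf("hypoglycemia < %g, hyperglycemia > %g mg/dL",
                          hypo, hyper))
  attr(p, "cgm_data") <- list(series = as_tibble(data),
                              thresholds = c(hypo = hypo, hyper = hyper))
  p
}

#' @rdname plot_band
#' @export
plot_smoothed <- function(data, fraction = 0.1, iterations = 2,
                          palette = cgm_palette) {
  data <- prep_series(data)
  sm <- lowess_smooth(data, fraction = fraction, iterations = iterations)
  p <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$glucose),
                       color = palette$trace, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                       color = palette$smooth, linewidth = 0.9) +
    cgm_plot_labs("Glucose with LOWESS smoothing",
                  sprintf("span %g, %g robustness iterations",
                          fraction, iterations))
  attr(p, "cgm_data") <- list(smoothed = sm)
  p
}

#' @rdname plot_band
#' @export
plot_by_day <- function(data, days = NULL, palette = cgm_palette) {
  data <- prep_series(data)
  df <- tibble(
    day = day_keys(data),
    tod_hours = as.numeric(difftime(
      data$time, lubridate::floor_date(data$time, "day"), units = "hours"
    )),
    glucose = data$glucose
  )
  available <- sort(unique(df$day))
  if (!is.null(days)) {
    days <- as.Date(days)
    missing_days <- days[!days %in% available]
    if (length(missing_days) > 0) {
      abort(
        sprintf("Day(s) %s not in the series. Available days: %s.",
                paste(missing_days, collapse = ", "),
                paste(available, collapse = ", ")),
        class = "cgm_parameter_error"
      )
    }
    df <- df[df$day %in% days, , drop = FALSE]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tod_hours,
                                        y = .data$glucose,
                                        color = factor(.data$day),
                                        group = .data$day)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 24, by = 6)) +
    ggplot2::labs(x = "time of day (h)", y = "glucose (mg/dL)",
                  color = "day",
                  title = "Glucose by time of day, one trace per day") +
    ggplot2::theme_minimal()
  attr(p, "cgm_data") <- list(by_day = df)
  p
}

cgm_plot_labs <- function(title, subtitle) {
  list(
    ggplot2::labs(x = "time", y = "glucose (mg/dL)", title = title,
                  subtitle = subtitle),
    ggplot2::theme_minimal()
  )
}

#' Autoplot method for CGM series
#'
#' Dispatches to one of the four plot functions; see [plot_band()].
#'
#' @param object A `cgm_series`.
#' @param type One of `"band"`, `"thresholds"`, `"smoothed"`, `"by_day"`.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @method autoplot cgm_series
#' @export
autoplot.cgm_series <- function(object, type = c("band", "thresholds",
                                                 "smoothed", "by_day"),
                                ...) {
  type <- match.arg(type)
  switch(type,
         band = plot_band(object, ...),
         thresholds = plot_thresholds(object, ...),
         smoothed = plot_smoothed(object, ...),
         by_day = plot_by_day(object, ...))
}

#' Extract the computed data layer of a CGM plot
#'
#' @param plot A ggplot returned by one of the `plot_*()` functions.
#' @return The list of tibbles the plot draws.
#' @export
plot_layer_data <- function(plot) {
  attr(plot, "cgm_data", exact = TRUE)
}

#' Save a CGM plot to an image file
#'
#' Thin wrapper over [ggplot2::ggsave()] defaulting to PNG; SVG is
#' available through the file extension.
#'
#' @param plot A ggplot object.
#' @param path Output path; the extension selects the device.
#' @param width,height,dpi Passed to `ggsave()`.
#' @return `path`, invisibly.
#' @export
save_cgm_plot <- function(plot, path, width = 9, height = 4, dpi = 150) {
  ggplot2::ggsave(path, plot = plot, width = width, height = height,
                  dpi = dpi)
  invisible(path)
}
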