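test_that("LOWESS reproduces linear and constant traces", {
  n <- 100
  g <- 100 + 0.2 * (0:(n - 1))
  s <- make_series(g)
  sm <- lowess_smooth(s, fraction = 0.2)
  expect_equal(sm$smoothed, g, tolerance = 1e-6)
  expect_equal(nrow(sm), n)

  const <- make_series(rep(130, 50))
  expect_equal(lowess_smooth(const)$smoothed, rep(130, 50))
})

test_that("LOWESS robustness iterations suppress a single outlier", {
  n <- 120
  g <- 100 + 0.3 * (0:(n - 1))
  g_out <- g
  g_out[60] <- g[60] + 150
  sm <- lowess_smooth(make_series(g_out), fraction = 0.3, iterations = 2)
  expect_lt(max(abs(sm$smoothed - g)), 150 / 10)
})

test_that("LOWESS validates its span", {
  s <- make_series(c(100, 110, 120, 130))
  expect_error(lowess_smooth(s, fraction = 0), class = "cgm_parameter_error")
  expect_error(lowess_smooth(s, fraction = 1.2),
               class = "cgm_parameter_error")
  expect_error(lowess_smooth(make_series(c(100, 110))),
               class = "cgm_parameter_error")
})

test_that("band plot draws the glucose_band edges and mean", {
  s <- random_series(31)
  p <- plot_band(s, k = 1.5)
  layer <- plot_layer_data(p)
  expect_equal(layer$band, glucose_band(s, 1.5))
  expect_equal(layer$mean, interday_mean(s))
  expect_s3_class(p, "ggplot")

  # data layer is a pure function of (series, parameters)
  p2 <- plot_band(s, k = 1.5)
  expect_equal(plot_layer_data(p2), layer)
})

test_that("threshold plot defaults to 70/180 mg/dL and validates order", {
  s <- random_series(32)
  p <- plot_thresholds(s)
  expect_equal(plot_layer_data(p)$thresholds, c(hypo = 70, hyper = 180))
  p2 <- plot_thresholds(s, hypo = 80, hyper = 160)
  expect_equal(plot_layer_data(p2)$thresholds, c(hypo = 80, hyper = 160))
  expect_error(plot_thresholds(s, hypo = 180, hyper = 70),
               class = "cgm_parameter_error")
})

test_that("smoothed plot overlays exactly lowess_smooth output", {
  s <- random_series(33)
  p <- plot_smoothed(s, fraction = 0.15)
  expect_equal(plot_layer_data(p)$smoothed,
               lowess_smooth(s, fraction = 0.15))
})

test_that("by-day plot folds days onto time of day", {
  s <- simulate_cgm(sim_profile(n_days = 3, seed = 7))
  p <- plot_by_day(s)
  df <- plot_layer_data(p)$by_day
  expect_equal(sort(unique(df$day)), cgm_days(s)$day)
  expect_true(all(df$tod_hours >= 0 & df$tod_hours < 24))

  one <- plot_by_day(s, days = cgm_days(s)$day[2])
  expect_equal(unique(plot_layer_data(one)$by_day$day), cgm_days(s)$day[2])

  err <- expect_error(plot_by_day(s, days = "2019-01-01"),
                      class = "cgm_parameter_error")
  expect_match(conditionMessage(err), "2023-03-01")  # lists available days
})

test_that("autoplot dispatches across plot kinds and plots can be saved", {
  s <- simulate_cgm(sim_profile(n_days = 2, seed = 9))
  for (kind in c("band", "thresholds", "smoothed", "by_day")) {
    expect_s3_class(autoplot(s, type = kind), "ggplot")
  }
  f <- withr::local_tempfile(fileext = ".png")
  save_cgm_plot(autoplot(s, type = "band"), f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
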