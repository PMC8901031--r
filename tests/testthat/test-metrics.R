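test_that("pooled summary statistics match direct arithmetic", {
  s <- make_series(c(100, 120, 140))
  expect_equal(interday_mean(s), 120)
  expect_equal(interday_median(s), 120)
  expect_equal(interday_sd(s), 20)
  expect_equal(interday_cv(s), 100 * 20 / 120)

  ss <- summary_stats(make_series(c(100, 110, 120, 130, 140)))
  expect_equal(ss$q1, 110)
  expect_equal(ss$q3, 130)
  expect_equal(ss$min, 100)
  expect_equal(ss$max, 140)

  const <- make_series(rep(120, 10))
  expect_equal(interday_sd(const), 0)
  expect_equal(interday_cv(const), 0)
  expect_equal(summary_stats(const)$q1, 120)
})

test_that("SD is scale-equivariant and CV scale-invariant", {
  s <- random_series(3)
  base <- make_series(s$glucose, interval_min = attr(s, "interval_min"))
  for (c_factor in c(0.5, 2)) {
    sc <- make_series(c_factor * s$glucose,
                      interval_min = attr(s, "interval_min"))
    expect_equal(interday_sd(sc), c_factor * interday_sd(base))
    expect_equal(interday_cv(sc), interday_cv(base))
  }
})

test_that("intraday dispersion is computed per day then aggregated", {
  # two internally constant days: intraday SD 0, interday SD > 0
  two_flat_days <- make_series(c(rep(100, 288), rep(140, 288)))
  isd <- intraday_sd(two_flat_days)
  expect_equal(isd$mean, 0)
  expect_equal(isd$sd, 0)
  expect_gt(interday_sd(two_flat_days), 0)

  # a single day: across-day SD undefined
  one_day <- make_series(c(100, 120, 140))
  isd1 <- intraday_sd(one_day)
  expect_true(is.na(isd1$sd))
  expect_match(attr(isd1, "cgm_reason"), "2 or more days")
  expect_equal(isd1$mean, 20)

  # all days thin
  thin <- make_series(c(100, 110), interval_min = 1440)
  expect_true(is.na(intraday_sd(thin)$mean))
})

test_that("band, time in range and their conservation laws", {
  s <- make_series(c(100, 120, 140))
  b <- glucose_band(s, k = 1)
  expect_equal(b$lower, 100)
  expect_equal(b$upper, 140)
  b0 <- glucose_band(s, k = 0)
  expect_equal(b0$lower, b0$upper)
  b2 <- glucose_band(s, k = 2)
  expect_equal(b2$upper - b2$lower, 2 * (b$upper - b$lower))

  # 288 readings, 200 inside a degenerate-width-friendly construction
  g <- c(rep(120, 200), rep(200, 50), rep(40, 38))
  x <- make_series(g)
  band <- glucose_band(x, 1)
  n_in <- sum(g >= band$lower & g <= band$upper)
  expect_equal(time_in_range(x), n_in * 5)
  expect_equal(time_in_range(x) + time_outside_range(x), length(g) * 5)
  expect_equal(percent_in_range(x) + percent_outside_range(x), 100)

  # constant series: degenerate band still contains everything
  const <- make_series(rep(120, 288))
  expect_equal(time_outside_range(const), 0)
  expect_equal(percent_in_range(const), 100)
})

test_that("clinical range times split total duration at 70/180 by default", {
  g <- c(60, 65, 69, 100, 120, 150, 70, 180, 181, 200)  # 3 below, 5 in, 2 above
  s <- make_series(g)
  ct <- clinical_range_times(s)
  expect_equal(ct$minutes_below, 15)
  expect_equal(ct$minutes_in, 25)
  expect_equal(ct$minutes_above, 10)
  expect_equal(ct$minutes_below + ct$minutes_in + ct$minutes_above,
               length(g) * 5)

  expect_equal(clinical_range_times(make_series(rep(120, 4)))$minutes_in, 20)
  expect_equal(clinical_range_times(make_series(rep(60, 4)))$minutes_below, 20)
  expect_error(clinical_range_times(s, hypo = 200, hyper = 100),
               class = "cgm_parameter_error")
})

test_that("MGE and MGN average the outside- and inside-band readings", {
  g <- c(rep(120, 6), 200, 210, 40, 45)
  s <- make_series(g)
  band <- glucose_band(s, 1)
  outside <- g[g < band$lower | g > band$upper]
  inside <- g[g >= band$lower & g <= band$upper]
  expect_equal(mge(s), mean(outside))
  expect_equal(mgn(s), mean(inside))
  expect_true(mgn(s) >= band$lower && mgn(s) <= band$upper)

  const <- make_series(rep(120, 5))
  expect_true(is_undefined_metric(mge(const)))
  expect_equal(mgn(const), 120)
})

test_that("J-index, GMI and eA1c follow their published formulas", {
  expect_equal(j_index(make_series(rep(140, 4))), 19.6)
  # mean 120, SD 20 -> same (mean + SD) sum
  expect_equal(j_index(make_series(c(100, 120, 140))), 19.6)

  expect_equal(gmi(make_series(rep(100, 4))), 5.702)
  expect_equal(ea1c(make_series(rep(126, 4))), 6.017, tolerance = 1e-4)
  expect_equal(ea1c(make_series(rep(154, 4))), 6.993, tolerance = 1e-4)

  # monotone in the mean; GMI depends on the mean only
  lo <- make_series(rep(100, 4))
  hi <- make_series(rep(150, 4))
  expect_gt(gmi(hi), gmi(lo))
  expect_gt(ea1c(hi), ea1c(lo))
  mixed <- make_series(c(90, 110))  # same mean as rep(100, .)
  expect_equal(gmi(mixed), gmi(lo))
})

test_that("risk transform has the Kovatchev structure", {
  rt <- risk_transform(make_series(c(50, 112.5, 300)))
  expect_equal(rt$rl * rt$rh, rep(0, 3))
  expect_lt(abs(rt$f[2]), 1e-2)      # ~root of the transform
  expect_equal(rt$rl[1], 22.5, tolerance = 0.5 / 22.5)
  expect_equal(rt$rh[1], 0)
  expect_gt(rt$rh[3], 0)
  expect_false(is.unsorted(rt$f))    # monotone in glucose
})

test_that("LBGI/HBGI sign structure and ADRR day maxima", {
  near_root <- make_series(rep(112.5, 600))
  expect_lt(lbgi(near_root), 1e-3)
  expect_lt(hbgi(near_root), 1e-3)
  expect_lt(adrr(near_root), 1e-3)

  high <- make_series(seq(115, 300, length.out = 50))
  expect_equal(lbgi(high), 0)
  expect_gt(hbgi(high), 0)
  low <- make_series(seq(40, 112, length.out = 50))
  expect_equal(hbgi(low), 0)

  # single-day ADRR is that day's LR + HR
  one_day <- make_series(c(60, 120, 250))
  r <- risk_transform(one_day)
  expect_equal(adrr(one_day), max(r$rl) + max(r$rh))

  # a high spike cannot decrease ADRR
  spiked <- make_series(c(60, 120, 250, 380))
  expect_gte(adrr(spiked), adrr(one_day))
})

test_that("MODD measures day-to-day differences via 24-h pairing", {
  periodic <- simulate_cgm(sim_profile(noise_sd = 0, n_days = 3, seed = 1))
  expect_equal(as.numeric(modd(periodic)), 0)

  # day 2 = day 1 + 10 everywhere
  day1 <- 100 + 20 * sin(2 * pi * seq(0, 1435, 5) / 1440)
  s <- make_series(c(day1, day1 + 10))
  expect_equal(as.numeric(modd(s)), 10)
  expect_equal(attr(modd(s), "n_pairs"), 288)

  expect_true(is_undefined_metric(modd(make_series(c(100, 120)))))
  expect_gte(as.numeric(modd(random_series(5))), 0)
})

test_that("CONGA is the SD of lagged differences", {
  periodic <- simulate_cgm(sim_profile(noise_sd = 0, n_days = 3, seed = 1))
  expect_equal(as.numeric(conga(periodic, 24)), 0)

  # linear ramp: all lagged differences equal -> SD 0
  ramp <- make_series(seq(80, 80 + 0.1 * 575, by = 0.1))  # 2 days of 5-min
  expect_equal(as.numeric(conga(ramp, 24)), 0)
  expect_equal(as.numeric(conga(ramp, 4)), 0)

  # brute-force enumeration on a 2-day fixture
  s <- random_series(8)
  tol <- attr(s, "interval_min") / 2
  expect_equal(as.numeric(conga(s, 24)), o_conga(s, 24, tol))
  expect_error(conga(s, n_hours = 0), class = "cgm_parameter_error")
})

test_that("undefined metrics carry their reason", {
  u <- interday_sd(make_series(100))
  expect_true(is_undefined_metric(u))
  expect_match(undefined_reason(u), "fewer than 2")
  expect_output(print(u), "undefined metric")
})
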