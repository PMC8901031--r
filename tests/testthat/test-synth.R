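test_that("simulation is deterministic given a seed and leaves the RNG alone", {
  p <- sim_profile(n_days = 2, seed = 99)
  a <- simulate_cgm(p)
  b <- simulate_cgm(p)
  expect_identical(a$glucose, b$glucose)
  expect_identical(a$time, b$time)

  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_cgm(p))
  expect_identical(runif(1), before)  # caller's RNG stream undisturbed
})

test_that("noiseless degenerate profiles are exact", {
  flat <- simulate_cgm(sim_profile(baseline = 100, circadian_amplitude = 0,
                                   meal_events = list(), noise_sd = 0,
                                   n_days = 2, seed = 1))
  expect_equal(unique(flat$glucose), 100)
  expect_equal(interday_sd(flat), 0)

  periodic <- simulate_cgm(sim_profile(noise_sd = 0, n_days = 3, seed = 1))
  expect_equal(as.numeric(modd(periodic)), 0)
  expect_equal(as.numeric(conga(periodic, 24)), 0)
})

test_that("pure-sine profile recovers baseline and amplitude/sqrt(2)", {
  s <- simulate_cgm(sim_profile(baseline = 120, circadian_amplitude = 40,
                                meal_events = list(), noise_sd = 0,
                                cadence_min = 5, n_days = 7, seed = 1))
  expect_equal(interday_mean(s), 120, tolerance = 0.5 / 120)
  expect_equal(interday_sd(s), 40 / sqrt(2), tolerance = 0.02)
})

test_that("meal pulses rise linearly then decay exponentially", {
  s <- simulate_cgm(sim_profile(baseline = 100, circadian_amplitude = 0,
                                meal_events = list(c(12, 80, 30, 60)),
                                noise_sd = 0, n_days = 1, seed = 1))
  at <- function(hhmm) {
    s$glucose[format(s$time, "%H:%M", tz = "UTC") == hhmm]
  }
  expect_equal(at("12:00"), 100)          # onset
  expect_equal(at("12:15"), 140)          # halfway up the linear rise
  expect_equal(at("12:30"), 180)          # peak
  expect_equal(at("13:30"), 100 + 80 * exp(-1), tolerance = 0.002)
})

test_that("gap windows remove readings without imputation", {
  s <- simulate_cgm(sim_profile(n_days = 1, noise_sd = 0,
                                gaps = list(c(2, 60), c(10, 30)), seed = 1))
  expect_equal(nrow(s), 288 - 12 - 6)
  expect_equal(nrow(find_gaps(s)), 2)
  expect_error(
    simulate_cgm(sim_profile(n_days = 1, gaps = list(c(0, 1e6)), seed = 1)),
    class = "cgm_parameter_error"
  )
})

test_that("profile validation rejects out-of-range parameters", {
  expect_error(sim_profile(baseline = 20), class = "cgm_parameter_error")
  expect_error(sim_profile(ar_coefficient = 1), class = "cgm_parameter_error")
  expect_error(sim_profile(cadence_min = 0), class = "cgm_parameter_error")
  expect_error(sim_profile(meal_events = list(c(25, 50, 30, 60))),
               class = "cgm_parameter_error")
  expect_warning(sim_profile(baseline = 45, circadian_amplitude = 40),
                 regexp = "clipped")
})

test_that("dialect emission round-trips through every reader", {
  s <- simulate_cgm(sim_profile(n_days = 1, cadence_min = 5, seed = 5))
  s15 <- simulate_cgm(sim_profile(n_days = 1, cadence_min = 15, seed = 5))

  f <- withr::local_tempfile(fileext = ".csv")
  emit_dialect(s, "dexcom", f)
  back <- read_dexcom_csv(f, quiet = TRUE)
  expect_equal(back$time, s$time)
  expect_equal(back$glucose, s$glucose)

  emit_dialect(s15, "libre", f)
  back <- read_libre_csv(f, quiet = TRUE)
  expect_equal(back$time, s15$time)
  expect_equal(back$glucose, s15$glucose)

  emit_dialect(s, "generic", f)
  back <- read_generic_csv(f, interval_min = 5, quiet = TRUE)
  expect_equal(back$time, s$time)
  expect_equal(back$glucose, s$glucose)

  expect_error(emit_dialect(s, "medtronic", f),
               class = "cgm_parameter_error")
})

test_that("emission is byte-deterministic", {
  s <- simulate_cgm(sim_profile(n_days = 1, seed = 17))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  emit_dialect(s, "dexcom", f1)
  emit_dialect(s, "dexcom", f2)
  expect_identical(readLines(f1), readLines(f2))
})
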