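# Fixture builders: everything is generated in code, no stored data files.

t0 <- function(date = "2023-03-01 00:00:00") as.POSIXct(date, tz = "UTC")

# Regularly sampled series from a glucose vector.
make_series <- function(glucose, interval_min = 5, start = t0(),
                        device = "test") {
  cgmetrics::as_cgm_series(
    data.frame(
      time = start + 60 * interval_min * (seq_along(glucose) - 1),
      glucose = glucose
    ),
    interval_min = interval_min, device = device
  )
}

# Triangle wave: linear up from `low` to `high` and back, `cycles` full
# cycles, `half_steps` readings per half-cycle. Peaks/troughs land exactly
# on samples.
triangle_series <- function(low = 100, high = 180, cycles = 8,
                            half_steps = 12, interval_min = 5) {
  up <- seq(low, high, length.out = half_steps + 1)
  down <- seq(high, low, length.out = half_steps + 1)[-1]
  one <- c(up[-1], down)
  make_series(c(low, rep(one, cycles)), interval_min = interval_min)
}

# Dexcom-dialect CSV with optional raw glucose strings (e.g. "High").
write_dexcom_fixture <- function(path, times, glucose) {
  lines <- c(
    "Index,Timestamp (YYYY-MM-DDThh:mm:ss),Event Type,Event Subtype,Source Device ID,Glucose Value (mg/dL)",
    "1,,FirstName,,,",
    "2,,LastName,,,",
    sprintf("%d,%s,EGV,,dev01,%s",
            seq_along(times) + 2L,
            format(times, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
            as.character(glucose))
  )
  writeLines(lines, path)
  path
}

write_libre_fixture <- function(path, times, glucose, record_type = 0) {
  lines <- c(
    "Glucose Data,Export,fixture",
    "Device,Serial Number,Device Timestamp,Record Type,Historic Glucose mg/dL,Scan Glucose mg/dL",
    sprintf("FreeStyle Libre,FX0,%s,%s,%s,",
            format(times, "%m-%d-%Y %H:%M", tz = "UTC"),
            as.character(record_type),
            as.character(glucose))
  )
  writeLines(lines, path)
  path
}

# Randomized simulation profiles for property and oracle tests; bounded so
# fixtures stay small (<= 600 readings).
random_profile <- function(seed) {
  set.seed(seed)
  cadence <- sample(c(5, 15), 1)
  n_days <- 2
  gaps <- if (stats::runif(1) < 0.5) {
    list(c(stats::runif(1, 1, 40), stats::runif(1, 30, 180)))
  }
  cgmetrics::sim_profile(
    baseline = stats::runif(1, 100, 160),
    circadian_amplitude = stats::runif(1, 5, 30),
    meal_events = list(
      c(stats::runif(1, 6, 10), stats::runif(1, 30, 90),
        stats::runif(1, 20, 40), stats::runif(1, 60, 150)),
      c(stats::runif(1, 17, 21), stats::runif(1, 30, 90),
        stats::runif(1, 20, 40), stats::runif(1, 60, 150))
    ),
    noise_sd = stats::runif(1, 1, 8),
    ar_coefficient = stats::runif(1, 0.3, 0.9),
    cadence_min = cadence, n_days = n_days, gaps = gaps, seed = seed
  )
}

random_series <- function(seed) cgmetrics::simulate_cgm(random_profile(seed))
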