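#' Define a synthetic CGM simulation profile
#'
#' Parameters of the synthetic glucose generator: a baseline level, a
#' 24-hour sinusoidal circadian component, daily meal excursions
#' (piecewise-linear rise, exponential decay), AR(1) sensor noise, the
#' sampling cadence, missing-data gaps and a seed. The defaults sketch a
#' plausible week of reasonably controlled glucose: baseline 120 mg/dL,
#' modest circadian swing, three daily meals, mildly autocorrelated sensor
#' noise.
#'
#' @param baseline Baseline glucose, mg/dL.
#' @param circadian_amplitude Amplitude of the 24-h sinusoid, mg/dL.
#' @param meal_events List of meal excursions, each a numeric vector
#'   `c(time_of_day_hours, peak_rise_mgdl, rise_min, decay_min)`:
#'   glucose climbs linearly to `peak_rise` over `rise_min` minutes from
#'   meal onset, then decays exponentially with time constant `decay_min`.
#'   Meals repeat every day.
#' @param noise_sd SD of the AR(1) noise innovations, mg/dL. 0 for a
#'   noiseless trace.
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`; CGM sensor error is
#'   strongly autocorrelated, so the default is 0.7.
#' @param cadence_min Sampling cadence in minutes: 5 (Dexcom-like), 15
#'   (Libre-like) or any positive value.
#' @param n_days Number of simulated days (>= 1).
#' @param gaps List of missing-data windows, each
#'   `c(start_hours_from_record_start, duration_min)`; readings inside a
#'   window are removed (never imputed).
#' @param start First timestamp of the record.
#' @param seed Integer seed; identical profile + seed gives an identical
#'   trace.
#' @return A `sim_profile` list.
#' @examples
#' sim_profile(baseline = 110, noise_sd = 0, n_days = 2, seed = 1)
#' @export
sim_profile <- function(baseline = 120, circadian_amplitude = 20,
                        meal_events = list(
                          c(8, 45, 30, 90),
                          c(13, 55, 30, 120),
                          c(19, 60, 40, 150)
                        ),
                        noise_sd = 5, ar_coefficient = 0.7, cadence_min = 5,
                        n_days = 7, gaps = NULL,
                        start = as.POSIXct("2023-03-01 00:00:00", tz = "UTC"),
                        seed = NULL) {
  check_num <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
    ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
      (if (strict_min) x > min else x >= min) && x <= max
    if (!ok) {
      abort(sprintf("`%s` must be a single number in [%g, %g].",
                    name, min, max),
            class = "cgm_parameter_error")
    }
  }
  check_num(baseline, "baseline", 40, 400)
  check_num(circadian_amplitude, "circadian_amplitude", 0)
  check_num(noise_sd, "noise_sd", 0)
  check_num(ar_coefficient, "ar_coefficient", 0, 1 - 1e-9)
  check_num(cadence_min, "cadence_min", 0, strict_min = TRUE)
  check_num(n_days, "n_days", 1)
  for (m in meal_events) {
    if (!is.numeric(m) || length(m) != 4 || m[1] < 0 || m[1] >= 24 ||
        m[3] <= 0 || m[4] <= 0) {
      abort(
        "Each meal event must be c(time_of_day_hours in [0, 24), peak_rise, rise_min > 0, decay_min > 0).",
        class = "cgm_parameter_error"
      )
    }
  }
  noise_floor <- if (noise_sd > 0) {
    3 * noise_sd / sqrt(1 - ar_coefficient^2)
  } else {
    0
  }
  if (baseline - circadian_amplitude - noise_floor <= 10) {
    warn(paste(
      "Profile can plausibly dip below the 10 mg/dL parser bound;",
      "simulated values will be clipped to [40, 400] mg/dL."
    ))
  }
  structure(
    list(baseline = baseline, circadian_amplitude = circadian_amplitude,
         meal_events = meal_events, noise_sd = noise_sd,
         ar_coefficient = ar_coefficient, cadence_min = cadence_min,
         n_days = n_days, gaps = gaps, start = start, seed = seed),
    class = "sim_profile"
  )
}

#' Simulate a synthetic CGM glucose series
#'
#' Generates `G(t) = baseline + circadian_amplitude * sin(2*pi*tod/24h) +
#' meal pulses + AR(1) noise`, clipped to the sensor-reportable range
#' \[40, 400\] mg/dL and quantized to 0.1 mg/dL (as real sensors report),
#' with readings inside the profile's gap windows removed. Deterministic
#' given the profile's seed. Meal pulses are a function of time of day, so
#' a noiseless profile is exactly 24-hour periodic — which is what makes
#' MODD and CONGA(24) identically zero on it, a useful calibration for
#' those metrics.
#'
#' @param profile A [sim_profile()].
#' @return A `cgm_series` with `device = "synthetic"`.
#' @examples
#' s <- simulate_cgm(sim_profile(n_days = 7, seed = 42))
#' cgm_metrics(s)
#' @export
simulate_cgm <- function(profile) {
  if (!inherits(profile, "sim_profile")) {
    abort("`profile` must come from sim_profile().",
          class = "cgm_parameter_error")
  }
  t_min <- seq(0, profile$n_days * 1440 - profile$cadence_min,
               by = profile$cadence_min)
  n <- length(t_min)
  tod_min <- t_min %% 1440

  g <- profile$baseline +
    profile$circadian_amplitude * sin(2 * pi * tod_min / 1440)
  for (m in profile$meal_events) {
    onset <- m[1] * 60
    u <- (t_min - onset) %% 1440
    pulse <- ifelse(u < m[3], m[2] * u / m[3],
                    m[2] * exp(-(u - m[3]) / m[4]))
    g <- g + pulse
  }
  if (profile$noise_sd > 0) {
    g <- g + with_preserved_rng(profile$seed, {
      innov <- stats::rnorm(n, 0, profile$noise_sd)
      e0 <- stats::rnorm(1, 0,
                         profile$noise_sd /
                           sqrt(1 - profile$ar_coefficient^2))
      as.numeric(stats::filter(innov, profile$ar_coefficient,
                               method = "recursive", init = e0))
    })
  }
  g <- round(pmin(400, pmax(40, g)), 1)

  keep <- rep(TRUE, n)
  for (gap in profile$gaps %||% list()) {
    keep[t_min >= gap[1] * 60 & t_min < gap[1] * 60 + gap[2]] <- FALSE
  }
  if (!any(keep)) {
    abort("Gap windows remove every reading.", class = "cgm_parameter_error")
  }
  new_cgm_series(
    profile$start + 60 * t_min[keep], g[keep],
    interval_min = profile$cadence_min, device = "synthetic"
  )
}

# Run code under a seed without disturbing the caller's RNG stream.
with_preserved_rng <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Write a glucose series in a device export dialect
#'
#' Emits a CSV in the Dexcom, Libre or generic (canonical) dialect that the
#' corresponding reader parses back to the identical series, so simulated
#' data can exercise the full import path. Output is byte-deterministic
#' given the series. Libre exports carry minute-resolution timestamps, so
#' that dialect requires a minute-aligned series (simulator output always
#' is).
#'
#' @inheritParams cgm_days
#' @param dialect `"dexcom"`, `"libre"` or `"generic"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' s <- simulate_cgm(sim_profile(n_days = 1, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' emit_dialect(s, "dexcom", f)
#' identical_series <- read_dexcom_csv(f, quiet = TRUE)
#' @export
emit_dialect <- function(data, dialect = c("dexcom", "libre", "generic"),
                         path) {
  dialect <- tryCatch(match.arg(dialect), error = function(e) {
    abort("`dialect` must be one of 'dexcom', 'libre', 'generic'.",
          class = "cgm_parameter_error")
  })
  data <- prep_series(data)
  if (dialect == "generic") {
    return(write_canonical_csv(data, path))
  }
  if (dialect == "dexcom") {
    lines <- c(
      "Index,Timestamp (YYYY-MM-DDThh:mm:ss),Event Type,Event Subtype,Source Device ID,Glucose Value (mg/dL)",
      "1,,FirstName,,,",
      "2,,LastName,,,",
      sprintf(
        "%d,%s,EGV,,synthetic-cgm,%s",
        seq_len(nrow(data)) + 2L,
        format(data$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
        format_glucose(data$glucose)
      )
    )
  } else {
    secs <- as.numeric(format(data$time, "%S", tz = "UTC"))
    if (any(secs != 0)) {
      warn("Libre dialect stores minute-resolution timestamps; seconds are truncated.")
    }
    lines <- c(
      "Glucose Data,Export,synthetic",
      "Device,Serial Number,Device Timestamp,Record Type,Historic Glucose mg/dL,Scan Glucose mg/dL",
      sprintf(
        "FreeStyle Libre,SYN000,%s,0,%s,",
        format(data$time, "%m-%d-%Y %H:%M", tz = "UTC"),
        format_glucose(data$glucose)
      )
    )
  }
  writeLines(lines, path)
  invisible(path)
}
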