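#' The package's metric surface
#'
#' Names of the 25 exported metric functions. Together they compute the 28
#' clinically validated metrics reported by [cgm_metrics()] (the intraday
#' SD and CV families each contribute three aggregated entries, and several
#' functions return multi-component summaries).
#'
#' @return Character vector of 25 function names.
#' @export
cgm_metric_surface <- function() {
  c(
    "interday_mean", "interday_median", "summary_stats", "interday_sd",
    "interday_cv", "intraday_sd", "intraday_cv", "glucose_band",
    "time_in_range", "time_outside_range", "percent_in_range",
    "percent_outside_range", "clinical_range_times", "mge", "mgn", "mage",
    "j_index", "risk_transform", "lbgi", "hbgi", "adrr", "modd", "conga",
    "gmi", "ea1c"
  )
}

# The canonical 28-entry report roster: name, units, and which family each
# entry belongs to. Config, not code, so the roster can be revised without
# touching cgm_metrics().
metric_roster <- function() {
  tibble(
    metric = c(
      "mean", "median", "min", "max", "q1", "q3",
      "interday_sd", "interday_cv",
      "intraday_sd_mean", "intraday_sd_median", "intraday_sd_sd",
      "intraday_cv_mean", "intraday_cv_median", "intraday_cv_sd",
      "tir", "tor", "por",
      "mge", "mgn", "mage", "j_index",
      "lbgi", "hbgi", "adrr", "modd", "conga",
      "gmi", "ea1c"
    ),
    units = c(
      rep("mg/dL", 6),
      "mg/dL", "%",
      rep("mg/dL", 3), rep("%", 3),
      "min", "min", "%",
      "mg/dL", "mg/dL", "mg/dL", "unitless",
      "unitless", "unitless", "unitless", "mg/dL", "mg/dL",
      "%A1c", "%A1c"
    )
  )
}

#' Compute the full 28-metric glycemic variability report
#'
#' Runs every metric in the canonical roster over a glucose series and
#' returns a tidy report: the six pooled summary statistics, interday SD
#' and CV, the three across-day aggregations each of intraday SD and CV,
#' band-based time in/outside range and percent outside range, MGE, MGN,
#' MAGE, J-index, LBGI, HBGI, ADRR, MODD, CONGA and the two A1c estimates
#' (GMI, eA1c) — 28 entries. Metrics that are undefined on the record (for
#' example MODD on a single day) appear with `value = NA` and the reason in
#' `note`, never silently omitted.
#'
#' @inheritParams interday_mean
#' @param k SD multiplier for the glucose band, MGE/MGN and MAGE threshold.
#' @param n_hours CONGA lag in hours (default 24).
#' @param sr Minutes represented by one reading; defaults to the nominal
#'   sampling interval.
#' @param smooth_window MAGE smoothing window in readings (odd).
#' @param pair_tolerance_min MODD/CONGA pairing tolerance; defaults to half
#'   the nominal interval.
#' @return A `cgm_report`: a 28-row tibble with columns `metric`, `value`,
#'   `units`, `params` (the parameters used, always echoed) and `note`
#'   (reason when undefined).
#' @examples
#' s <- simulate_cgm(sim_profile(n_days = 7, seed = 42))
#' cgm_metrics(s)
#' @export
cgm_metrics <- function(data, k = 1, n_hours = 24, sr = NULL,
                        smooth_window = 9, pair_tolerance_min = NULL) {
  data <- prep_series(data)
  sr_used <- resolve_sr(data, sr)
  tol_used <- pair_tolerance_min %||% (series_interval(data) / 2)

  ss <- summary_stats(data)
  isd <- intraday_sd(data)
  icv <- intraday_cv(data)
  band_ok <- nrow(data) >= 2

  val <- list()
  note <- list()
  add <- function(name, x) {
    if (is_undefined_metric(x)) {
      val[[name]] <<- NA_real_
      note[[name]] <<- undefined_reason(x)
    } else {
      val[[name]] <<- as.numeric(x)
      note[[name]] <<- NA_character_
    }
  }
  add_agg <- function(prefix, agg) {
    for (comp in c("mean", "median", "sd")) {
      name <- paste0(prefix, "_", comp)
      val[[name]] <<- agg[[comp]]
      note[[name]] <<- if (is.na(agg[[comp]])) {
        attr(agg, "cgm_reason") %||% "undefined"
      } else {
        NA_character_
      }
    }
  }

  add("mean", ss$mean)
  add("median", ss$median)
  add("min", ss$min)
  add("max", ss$max)
  add("q1", ss$q1)
  add("q3", ss$q3)
  add("interday_sd", interday_sd(data))
  add("interday_cv", interday_cv(data))
  add_agg("intraday_sd", isd)
  add_agg("intraday_cv", icv)
  if (band_ok) {
    add("tir", time_in_range(data, k, sr_used))
    add("tor", time_outside_range(data, k, sr_used))
    add("por", percent_outside_range(data, k, sr_used))
    add("mge", mge(data, k))
    add("mgn", mgn(data, k))
  } else {
    u <- undefined_metric("band undefined with fewer than 2 readings")
    for (nm in c("tir", "tor", "por", "mge", "mgn")) add(nm, u)
  }
  add("mage", mage(data, k = k, smooth_window = smooth_window))
  add("j_index", j_index(data))
  add("lbgi", lbgi(data))
  add("hbgi", hbgi(data))
  add("adrr", adrr(data))
  add("modd", modd(data, pair_tolerance_min = pair_tolerance_min))
  add("conga", conga(data, n_hours = n_hours,
                     pair_tolerance_min = pair_tolerance_min))
  add("gmi", gmi(data))
  add("ea1c", ea1c(data))

  params_for <- function(metric) {
    switch(
      metric,
      tir = , tor = , por = sprintf("k=%g;sr=%g", k, sr_used),
      mge = , mgn = sprintf("k=%g", k),
      mage = sprintf("k=%g;smooth_window=%g", k, smooth_window),
      modd = sprintf("lag_hours=24;pair_tolerance_min=%g", tol_used),
      conga = sprintf("lag_hours=%g;pair_tolerance_min=%g", n_hours,
                      tol_used),
      sprintf("sr=%g", sr_used)
    )
  }

  roster <- metric_roster()
  out <- tibble(
    metric = roster$metric,
    value = unname(vapply(roster$metric, function(m) val[[m]], numeric(1))),
    units = roster$units,
    params = unname(vapply(roster$metric, params_for, character(1))),
    note = unname(vapply(roster$metric, function(m) note[[m]], character(1)))
  )
  class(out) <- c("cgm_report", class(out))
  attr(out, "series_info") <- list(
    n = nrow(data), device = attr(data, "device") %||% "unknown",
    interval_min = series_interval(data)
  )
  attr(out, "params") <- list(k = k, n_hours = n_hours, sr = sr_used,
                              smooth_window = smooth_window,
                              pair_tolerance_min = tol_used)
  out
}

#' Tidy and one-row views of a metric report
#'
#' `tidy()` returns the report as a plain tibble (one row per metric);
#' `glance()` pivots it to a single wide row keyed by metric name, handy
#' for binding reports from many subjects.
#'
#' @param x A `cgm_report` from [cgm_metrics()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cgm_report
#' @export
tidy.cgm_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cgm_report")
  as_tibble(out)
}

#' @rdname tidy.cgm_report
#' @method glance cgm_report
#' @export
glance.cgm_report <- function(x, ...) {
  wide <- as.list(x$value)
  names(wide) <- x$metric
  as_tibble(wide)
}

#' Serialize a metric report
#'
#' CSV output has the documented field order `metric,value,units,params,
#' note`; JSON output is an array of per-metric objects with the same
#' fields plus the report-level parameters and series provenance.
#'
#' @param report A `cgm_report`.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  if (format == "csv") {
    readr::write_csv(
      tidy(report)[, c("metric", "value", "units", "params", "note")], path
    )
  } else if (format == "json") {
    jsonlite::write_json(
      list(
        params = attr(report, "params"),
        series = attr(report, "series_info"),
        metrics = tidy(report)
      ),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  } else {
    abort("`format` must be 'csv' or 'json'.", class = "cgm_parameter_error")
  }
  invisible(path)
}
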