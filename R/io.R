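# Device export dialects. Column headers and the record-type filter are
# data, not code, so a firmware revision that renames a column is a config
# change here.
cgm_dialects <- list(
  dexcom = list(
    timestamp = "Timestamp (YYYY-MM-DDThh:mm:ss)",
    glucose = "Glucose Value (mg/dL)",
    record_type = "Event Type",
    keep = "EGV",
    interval_min = 5
  ),
  libre = list(
    timestamp = "Device Timestamp",
    glucose = "Historic Glucose mg/dL",
    record_type = "Record Type",
    keep = "0",
    interval_min = 15
  )
)

#' Read a Dexcom CSV export
#'
#' Parses the Dexcom export dialect (metadata rows before the glucose
#' records, ISO timestamps, glucose in mg/dL) into a canonical
#' [cgm_series][as_cgm_series]. Only estimated-glucose (`EGV`) rows carry
#' readings; calibration rows and `"Low"`/`"High"` sensor-saturation flags
#' are dropped and counted in the parse log. Rows are sorted by timestamp
#' and exact-duplicate timestamps deduplicated keeping the first.
#'
#' @param path Path to the export CSV.
#' @param quiet Suppress the one-line parse log message.
#' @return A `cgm_series` with `interval_min = 5` and `device = "dexcom"`.
#' @seealso [read_libre_csv()], [read_generic_csv()], [write_canonical_csv()]
#' @export
read_dexcom_csv <- function(path, quiet = FALSE) {
  read_dialect_csv(path, "dexcom", quiet = quiet)
}

#' Read an Abbott FreeStyle Libre CSV export
#'
#' Parses the Libre export dialect. Only historic-glucose rows (record type
#' 0, the sensor's ~15-minute automatic log) are retained; scan and note
#' rows are dropped and counted. Canonicalization is as in
#' [read_dexcom_csv()].
#'
#' @inheritParams read_dexcom_csv
#' @return A `cgm_series` with `interval_min = 15` and `device = "libre"`.
#' @export
read_libre_csv <- function(path, quiet = FALSE) {
  read_dialect_csv(path, "libre", quiet = quiet)
}

read_dialect_csv <- function(path, dialect, quiet = FALSE) {
  cfg <- cgm_dialects[[dialect]]
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "cgm_input_error")
  }
  head_lines <- readLines(path, n = 100, warn = FALSE)
  header_at <- which(grepl(cfg$timestamp, head_lines, fixed = TRUE))[1]
  if (is.na(header_at)) {
    abort(
      sprintf(
        "'%s' is not in the %s export dialect: no header row with columns '%s' and '%s'.",
        path, dialect, cfg$timestamp, cfg$glucose
      ),
      class = "cgm_format_error"
    )
  }
  raw <- readr::read_csv(path, skip = header_at - 1, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c(cfg$glucose, cfg$record_type) %in% names(raw))) {
    abort(
      sprintf(
        "'%s' lacks expected %s columns '%s'/'%s'; found: %s.",
        path, dialect, cfg$glucose, cfg$record_type,
        paste0("'", names(raw), "'", collapse = ", ")
      ),
      class = "cgm_format_error"
    )
  }
  rows_read <- nrow(raw)
  raw <- raw[!is.na(raw[[cfg$record_type]]) &
               trimws(raw[[cfg$record_type]]) == cfg$keep, , drop = FALSE]
  if (nrow(raw) == 0) {
    abort(
      sprintf(
        "'%s' contains no %s glucose record rows ('%s' == '%s').",
        path, dialect, cfg$record_type, cfg$keep
      ),
      class = "cgm_format_error"
    )
  }
  series <- as_cgm_series(raw, time_col = cfg$timestamp,
                          glucose_col = cfg$glucose,
                          interval_min = cfg$interval_min, device = dialect)
  log <- attr(series, "parse_log")
  log$rows_read <- rows_read
  log$rows_filtered <- rows_read - nrow(raw)
  attr(series, "parse_log") <- log
  if (!quiet) {
    inform(sprintf(
      "%s: read %d rows, kept %d readings (%d non-record rows filtered, %d non-numeric dropped, %d duplicate timestamps removed)",
      dialect, rows_read, nrow(series), log$rows_filtered,
      log$dropped_nonnumeric, log$duplicates_removed
    ))
  }
  series
}

#' Read a generic two-column CSV
#'
#' For data from any other source: the caller names the timestamp and
#' glucose columns and declares the nominal sampling cadence. Lines starting
#' with `#` are treated as comments, so the output of
#' [write_canonical_csv()] reads back directly.
#'
#' @inheritParams read_dexcom_csv
#' @param timestamp_col,glucose_col Column names in the file.
#' @param interval_min Declared sampling cadence in minutes (> 0).
#' @return A `cgm_series` with `device = "generic"`.
#' @export
read_generic_csv <- function(path, timestamp_col = "time",
                             glucose_col = "glucose", interval_min = 5,
                             quiet = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "cgm_input_error")
  }
  if (!is.numeric(interval_min) || length(interval_min) != 1 ||
      !is.finite(interval_min) || interval_min <= 0) {
    abort("`interval_min` must be a single positive number.",
          class = "cgm_parameter_error")
  }
  raw <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  series <- as_cgm_series(raw, time_col = timestamp_col,
                          glucose_col = glucose_col,
                          interval_min = interval_min, device = "generic")
  if (!quiet) {
    log <- attr(series, "parse_log")
    inform(sprintf(
      "generic: read %d rows, kept %d readings (%d non-numeric dropped, %d duplicate timestamps removed)",
      nrow(raw), nrow(series), log$dropped_nonnumeric, log$duplicates_removed
    ))
  }
  series
}

#' Write a glucose series as canonical interchange CSV
#'
#' Writes a two-column CSV (ISO-8601 timestamp, glucose in mg/dL) preceded
#' by `#`-prefixed comment lines recording the device label and nominal
#' interval. [read_generic_csv()] on the output reproduces the series
#' exactly.
#'
#' @inheritParams cgm_days
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_canonical_csv <- function(data, path) {
  data <- prep_series(data)
  if (nrow(data) == 0) {
    abort("Cannot write an empty series.", class = "cgm_parameter_error")
  }
  lines <- c(
    sprintf("# device: %s", attr(data, "device") %||% "generic"),
    sprintf("# interval_min: %g", series_interval(data)),
    "time,glucose",
    sprintf("%s,%s", format(data$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
            format_glucose(data$glucose))
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) {
    abort(sprintf("Cannot write to '%s'.", path), class = "cgm_input_error")
  }
  invisible(path)
}

# 15 significant digits: exact round-trip for sensor-quantized values and
# lossless at any tolerance the package tests.
format_glucose <- function(x) sprintf("%.15g", x)
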