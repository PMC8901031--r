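#' Undefined metric values
#'
#' Some metrics are undefined on some records: MODD needs readings 24 h
#' apart, MAGE needs an excursion exceeding its threshold, an across-day SD
#' needs at least two days. Rather than a bare `NaN`, such results are a
#' typed `NA` carrying the reason, so reports stay auditable.
#'
#' @param reason Character explanation of why the value is undefined.
#' @return For `undefined_metric()`, an `NA` of class `cgm_undefined` with
#'   the reason attached; `is_undefined_metric()` tests for it;
#'   `undefined_reason()` extracts the reason (or `NA_character_`).
#' @examples
#' x <- undefined_metric("no 24-h pairs")
#' is_undefined_metric(x)
#' undefined_reason(x)
#' @export
undefined_metric <- function(reason) {
  structure(NA_real_, cgm_reason = reason,
            class = c("cgm_undefined", "numeric"))
}

#' @rdname undefined_metric
#' @param x An object.
#' @export
is_undefined_metric <- function(x) inherits(x, "cgm_undefined")

#' @rdname undefined_metric
#' @export
undefined_reason <- function(x) {
  attr(x, "cgm_reason", exact = TRUE) %||% NA_character_
}

#' @export
print.cgm_undefined <- function(x, ...) {
  cat(sprintf("<undefined metric: %s>\n", undefined_reason(x)))
  invisible(x)
}
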