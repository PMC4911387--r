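#' Construct a sampled time series
#'
#' The package's common carrier for sampled signals (plasma concentration,
#' effect-compartment concentration, dopaminergic input, tapping frequency)
#' is a tibble with a `time` column in minutes and a `value` column, plus a
#' `unit` attribute. Times must be strictly increasing.
#'
#' @param time Sample times \[min\], strictly increasing.
#' @param value Sampled values, same length as `time`.
#' @param unit Unit string carried as metadata (e.g. `"ug/ml"`,
#'   `"taps/min"`, `"dimensionless"`).
#' @return A tibble with columns `time` and `value` and attribute `unit`.
#' @examples
#' ts_series(c(0, 15, 30), c(0, 0.4, 1.1), unit = "ug/ml")
#' @export
ts_series <- function(time, value, unit = "dimensionless") {
  if (length(time) != length(value)) {
    stop("ts_series: `time` and `value` must have equal length", call. = FALSE)
  }
  if (length(time) && any(diff(time) <= 0)) {
    stop("ts_series: `time` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(!is.finite(value))) {
    stop("ts_series: non-finite entries", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(time), value = as.numeric(value))
  attr(out, "unit") <- unit
  out
}

#' Unit metadata of a time series
#' @param x A tibble produced by [ts_series()] or a reader.
#' @return The unit string, or `"dimensionless"` when absent.
#' @export
ts_unit <- function(x) {
  u <- attr(x, "unit", exact = TRUE)
  if (is.null(u)) "dimensionless" else u
}

assert_ts <- function(x, what = "series", non_negative = FALSE) {
  if (!is.data.frame(x) || !all(c("time", "value") %in% names(x))) {
    stop(what, " must be a data frame with `time` and `value` columns",
         call. = FALSE)
  }
  if (nrow(x) && any(diff(x$time) <= 0)) {
    stop(what, ": `time` must be strictly increasing", call. = FALSE)
  }
  if (non_negative && any(x$value < 0)) {
    stop(what, ": values must be non-negative", call. = FALSE)
  }
  invisible(x)
}

# linear interpolation with constant extension at both ends
ts_interp <- function(x, t_out) {
  stats::approx(x$time, x$value, xout = t_out, method = "linear",
                rule = 2)$y
}
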