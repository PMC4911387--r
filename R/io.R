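#' Read a sampled time series from CSV
#'
#' Expects a header with a `time_min` column and exactly one value column
#' (e.g. `conc_ug_ml`, `taps_per_min`). Rows must be numeric, times
#' strictly increasing without duplicates; concentration-valued series
#' must be non-negative. Errors name the offending line (header = line 1).
#'
#' @param path CSV file path.
#' @param expected_unit Optional unit tag; when supplied it must match the
#'   value column (`conc_ug_ml` for `"ug/ml"`, `taps_per_min` for
#'   `"taps/min"`), and it is attached to the result.
#' @return A tibble with `time`, `value` and a `unit` attribute.
#' @export
read_timeseries <- function(path, expected_unit = NULL) {
  if (!file.exists(path)) stop("read_timeseries: no such file: ", path,
                               call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_min" %in% names(df)) {
    stop("read_timeseries: header must contain `time_min` (", path, ")",
         call. = FALSE)
  }
  value_col <- setdiff(names(df), "time_min")
  if (length(value_col) != 1L) {
    stop("read_timeseries: expected exactly one value column besides ",
         "`time_min`, found: ", paste(value_col, collapse = ", "),
         call. = FALSE)
  }
  unit <- switch(value_col,
                 conc_ug_ml = "ug/ml",
                 taps_per_min = "taps/min",
                 D = "dimensionless",
                 "dimensionless")
  if (!is.null(expected_unit) && !identical(unit, expected_unit)) {
    stop("read_timeseries: file carries `", value_col, "` (", unit,
         ") but `", expected_unit, "` was expected", call. = FALSE)
  }
  tt <- df$time_min
  vv <- df[[value_col]]
  bad <- which(!is.finite(tt) | !is.finite(vv))
  if (length(bad)) {
    stop("read_timeseries: malformed row at line ", bad[1] + 1L, " of ",
         path, call. = FALSE)
  }
  if (anyDuplicated(tt)) {
    dup <- which(duplicated(tt))[1]
    stop("read_timeseries: duplicate time at line ", dup + 1L, " of ", path,
         call. = FALSE)
  }
  nonmono <- which(diff(tt) <= 0)
  if (length(nonmono)) {
    stop("read_timeseries: non-monotone times at line ", nonmono[1] + 2L,
         " of ", path, call. = FALSE)
  }
  if (unit == "ug/ml" && any(vv < 0)) {
    neg <- which(vv < 0)[1]
    stop("read_timeseries: negative concentration at line ", neg + 1L,
         " of ", path, call. = FALSE)
  }
  ts_series(tt, vv, unit = unit)
}

#' Write a sampled time series to CSV
#'
#' Inverse of [read_timeseries()]: writes `time_min` plus a value column
#' named after the unit (`conc_ug_ml`, `taps_per_min`, or `value`).
#'
#' @param x A tibble with `time` and `value` columns (unit attribute
#'   honoured).
#' @param path Output CSV path.
#' @param unit Overrides the unit attribute when supplied.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, unit = NULL) {
  assert_ts(x, "series")
  unit <- unit %||% ts_unit(x)
  col <- switch(unit, "ug/ml" = "conc_ug_ml", "taps/min" = "taps_per_min",
                "value")
  df <- stats::setNames(tibble::tibble(x$time, x$value), c("time_min", col))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Load a parameter set from YAML or JSON
#'
#' Reads a parameter document and validates it against the requested type.
#' Field names mirror the parameter tables (`k21`, `k12`, `ketot`, `V1`,
#' `V2`; `ke3_over_V3`, `T`, `D0`, `Dmax`, `Dc50`, `N`, `k31_over_V3`;
#' the network constants and weights of [bg_params()]/[bg_weights()]).
#' Wrong-sign synaptic weights and missing fields raise validation errors
#' naming the field.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @param type One of `"pk"`, `"effect"`, `"bg"`, `"weights"`.
#' @return The corresponding parameter object.
#' @export
load_params <- function(path, type = c("pk", "effect", "bg", "weights")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("load_params: no such file: ", path,
                               call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(doc)) stop("load_params: document must be a mapping",
                          call. = FALSE)
  doc <- lapply(doc, as.numeric)
  switch(type,
    pk = do.call(pk_params, doc[intersect(names(doc),
                                          c("k12", "k21", "ketot", "V1", "V2"))]),
    effect = {
      if ("T" %in% names(doc) && !"T_delay" %in% names(doc)) {
        doc$T_delay <- doc$T
        doc$T <- NULL
      }
      # YAML 1.1 reads a bare `N:`/`T:` key as a boolean; map it back
      if ("FALSE" %in% names(doc) && !"N" %in% names(doc)) {
        names(doc)[names(doc) == "FALSE"] <- "N"
      }
      if ("TRUE" %in% names(doc) && !"T_delay" %in% names(doc)) {
        names(doc)[names(doc) == "TRUE"] <- "T_delay"
      }
      do.call(effect_params,
              doc[intersect(names(doc),
                            c("ke3_over_V3", "T_delay", "D0", "Dmax",
                              "Dc50", "N", "k31_over_V3"))])
    },
    bg = do.call(bg_params, doc[intersect(names(doc), names(formals(bg_params)))]),
    weights = do.call(bg_weights,
                      doc[intersect(names(doc), names(formals(bg_weights)))])
  )
}

#' Write a run manifest
#'
#' Records the configuration, package version and seed of a run alongside
#' its outputs, so any result can be reproduced from the manifest alone.
#'
#' @param path Output JSON path.
#' @param config Named list of run configuration entries.
#' @param seed The RNG seed used (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL) {
  manifest <- list(
    package = "levotap",
    version = as.character(utils::packageVersion("levotap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
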