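#' Assemble a patient record
#'
#' Bundles everything needed to replay a levodopa test for one subject:
#' dosing schedule, plasma pharmacokinetic constants, effect/Hill
#' constants, group label, and (optionally) observed plasma and tapping
#' series.
#'
#' @param id Subject identifier.
#' @param group 1 (no motor fluctuations) or 2 (motor fluctuations).
#' @param pk A [pk_params()].
#' @param effect An [effect_params()].
#' @param schedule An [infusion_schedule()].
#' @param observed_plasma,observed_tapping Optional observed series
#'   (tibbles with `time`, `value`).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(id, group, pk, effect,
                           schedule = infusion_schedule(1e5, 30),
                           observed_plasma = NULL, observed_tapping = NULL) {
  validate_pk_params(pk)
  validate_effect_params(effect)
  stopifnot(inherits(schedule, "infusion_schedule"))
  if (!group %in% c(1L, 2L)) {
    stop("patient_record: `group` must be 1 or 2", call. = FALSE)
  }
  if (!is.null(observed_plasma)) assert_ts(observed_plasma, "observed_plasma",
                                           non_negative = TRUE)
  if (!is.null(observed_tapping)) assert_ts(observed_tapping, "observed_tapping")
  structure(list(id = id, group = as.integer(group), pk = pk, effect = effect,
                 schedule = schedule, observed_plasma = observed_plasma,
                 observed_tapping = observed_tapping),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$id, " group", x$group, "\n")
  print(x$pk); print(x$effect)
  invisible(x)
}

#' Records for the six modelled patients
#'
#' Builds [patient_record()] objects from the parameter table of
#' [ld_patients()], with a common standardised oral dose (100 mg levodopa
#' over a 30 min absorption window by default).
#'
#' @param dose_ug Administered dose \[µg\].
#' @param duration_min Absorption window \[min\].
#' @param ... Passed to [effect_params()] (e.g. `k31_over_V3`).
#' @return A named list of `patient_record` objects (`"g1s1"`, ...).
#' @examples
#' recs <- ld_patient_records()
#' names(recs)
#' @export
ld_patient_records <- function(dose_ug = 1e5, duration_min = 30, ...) {
  tab <- ld_patients()
  sched <- infusion_schedule(dose_ug, duration_min)
  recs <- purrr::pmap(tab, function(group, subject, k21, k12, ketot, F_val,
                                    ke3_over_V3, T_delay, D0, Dmax, Dc50, N) {
    patient_record(
      id = sprintf("g%ds%d", group, subject), group = group,
      pk = pk_params(k12 = k12, k21 = k21, ketot = ketot),
      effect = effect_params(ke3_over_V3 = ke3_over_V3, T_delay = T_delay,
                             D0 = D0, Dmax = Dmax, Dc50 = Dc50, N = N, ...),
      schedule = sched
    )
  })
  stats::setNames(recs, purrr::map_chr(recs, "id"))
}

#' End-to-end patient simulation
#'
#' Chains dose -> plasma -> effect compartment -> dopaminergic input ->
#' tapping frequency for one patient over the clinical observation window:
#' [simulate_plasma()], [effect_chain()], then either interpolation of a
#' precomputed dopamine-to-frequency curve (`mode = "curve"`, the default,
#' built once via [d_to_frequency_curve()]) or a direct network run per
#' sample (`mode = "direct"`). The pre-dose tapping value corresponds to
#' the basal input `D0`.
#'
#' @param record A [patient_record()].
#' @param sample_times Output times \[min\], covering 0-240 by default.
#' @param mode `"curve"` (fast lookup) or `"direct"` (network run per
#'   sample).
#' @param curve Optional precomputed `d_curve`; built automatically when
#'   absent.
#' @param curve_grid Grid used when building the curve.
#' @param protocol,params,weights Network configuration for the tapping
#'   simulation; `sigma_noise` is forced to 0 (deterministic clinical
#'   replay).
#' @param sim_dt Internal plasma/effect sampling step \[min\].
#' @return A tibble of class `patient_sim` with columns `time`, `c1`,
#'   `c3delay`, `D`, `taps_per_min`, and the record attached as attribute
#'   `record`.
#' @examples
#' rec <- ld_patient_records()[["g1s2"]]
#' sim <- simulate_patient(rec, sample_times = seq(0, 240, by = 30),
#'                         curve_grid = seq(0.1, 0.65, by = 0.05))
#' sim
#' @export
simulate_patient <- function(record, sample_times = seq(0, 240, by = 15),
                             mode = c("curve", "direct"), curve = NULL,
                             curve_grid = seq(0.05, 0.8, by = 0.025),
                             protocol = tapping_protocol(),
                             params = bg_params(), weights = bg_weights(),
                             sim_dt = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "patient_record"))
  if (min(sample_times) < 0 || max(sample_times) > 1440) {
    stop("simulate_patient: sample times must lie within one day", call. = FALSE)
  }
  params$sigma_noise <- 0
  # dense internal grid for the kinetics, then read off at sample times
  dense_t <- seq(0, max(sample_times), by = sim_dt)
  dense_t <- sort(unique(c(dense_t, sample_times)))
  plasma <- simulate_plasma(record$pk, record$schedule, dense_t)
  chain <- effect_chain(plasma, record$effect)

  idx <- match(sample_times, chain$time)
  D_samp <- chain$D[idx]

  if (mode == "curve") {
    if (is.null(curve)) {
      grid <- sort(unique(c(curve_grid, record$effect$D0)))
      curve <- d_to_frequency_curve(grid, protocol, params, weights)
    }
    taps <- frequency_lookup(curve, D_samp)
  } else {
    taps <- purrr::map_dbl(D_samp, function(D) {
      run_tapping(D, protocol, params, weights)$frequency_tpm
    })
  }

  out <- tibble::tibble(
    time = sample_times,
    c1 = plasma$c1[match(sample_times, plasma$time)],
    c3delay = chain$c3delay[idx],
    D = D_samp,
    taps_per_min = taps
  )
  attr(out, "record") <- record
  attr(out, "curve") <- curve
  class(out) <- c("patient_sim", class(out))
  out
}

#' Clinical response metrics of a tapping series
#'
#' Implements the levodopa-test response definitions: latency is the first
#' time the tapping frequency rises to at least 15% above baseline; the
#' response ends at the first later return below that band; duration is
#' the difference. A patient whose tapping has not returned to within 15%
#' of baseline by the end of the observation window is a "stable"
#' responder; a return within the window marks a "wearing-off" responder.
#' A series that never rises 15% above baseline is a no-response result.
#'
#' @param tapping A data frame with `time` \[min\] and `value` or
#'   `taps_per_min` column.
#' @param baseline Pre-dose tapping frequency \[taps/min\]; defaults to the
#'   value at the earliest sample time.
#' @param window End of the observation window \[min\] (4 h default).
#' @param rise_frac Response band as a fraction of baseline (0.15).
#' @return An object of class `response_metrics`: `baseline`, `latency`,
#'   `offset`, `duration` (NA when open-ended), `responded`,
#'   `classification` (`"stable"`, `"wearing-off"` or `"no-response"`).
#' @examples
#' tap <- tibble::tibble(time = c(0, 30, 60, 90, 120),
#'                       value = 100 * c(1, 1.2, 1.3, 1.2, 1.1))
#' response_metrics(tap, baseline = 100, window = 240)
#' @export
response_metrics <- function(tapping, baseline = NULL, window = 240,
                             rise_frac = 0.15) {
  if ("taps_per_min" %in% names(tapping) && !"value" %in% names(tapping)) {
    tapping <- dplyr::rename(tapping, value = "taps_per_min")
  }
  assert_ts(tapping, "tapping")
  if (is.null(baseline)) baseline <- tapping$value[1]
  if (baseline <= 0) stop("response_metrics: baseline must be positive",
                          call. = FALSE)
  tt <- tapping$time[tapping$time <= window]
  vv <- tapping$value[tapping$time <= window]
  band <- (1 + rise_frac) * baseline

  up <- which(vv >= band)
  if (!length(up)) {
    return(structure(list(baseline = baseline, latency = NA_real_,
                          offset = NA_real_, duration = NA_real_,
                          responded = FALSE,
                          classification = "no-response"),
                     class = "response_metrics"))
  }
  latency <- tt[up[1]]
  after <- which(tt > latency & vv < band)
  if (length(after)) {
    offset <- tt[after[1]]
    cls <- "wearing-off"
    duration <- offset - latency
  } else {
    offset <- NA_real_
    cls <- "stable"
    duration <- NA_real_
  }
  structure(list(baseline = baseline, latency = latency, offset = offset,
                 duration = duration, responded = TRUE,
                 classification = cls),
            class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat("<response_metrics>  baseline =", round(x$baseline, 1), "taps/min;")
  if (!x$responded) {
    cat(" no response (never rose >= 15% above baseline)\n")
  } else {
    cat(" latency =", x$latency, "min;",
        if (is.na(x$offset)) "no return within window;" else
          paste("offset =", x$offset, "min; duration =", x$duration, "min;"),
        x$classification, "\n")
  }
  invisible(x)
}

#' Tidy response metrics
#' @param x A `response_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy response_metrics
#' @export
tidy.response_metrics <- function(x, ...) {
  tibble::tibble(
    baseline = x$baseline, latency = x$latency, offset = x$offset,
    duration = x$duration, responded = x$responded,
    classification = x$classification
  )
}

#' Map response metrics to a patient group archetype
#'
#' Deterministic mapping of the stable/wearing-off classification to the
#' clinical group labels: stable responders to group 1 (no motor
#' fluctuations), wearing-off responders to group 2 (motor fluctuations).
#' A no-response input is unclassified.
#'
#' @param metrics A [response_metrics()] result.
#' @return Integer group label (1, 2) or `NA` for unclassified.
#' @export
classify_group <- function(metrics) {
  stopifnot(inherits(metrics, "response_metrics"))
  switch(metrics$classification,
         "stable" = 1L,
         "wearing-off" = 2L,
         NA_integer_)
}
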