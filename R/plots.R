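#' Plot cortical activity traces of a tapping run
#'
#' One panel per cortical unit (channel 1 = tap down, channel 2 = lift and
#' shift), with the action threshold marked. Requires the run to have been
#' made with `record_traces = TRUE`.
#'
#' @param object A `tap_result` from [run_tapping()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot tap_result
#' @export
autoplot.tap_result <- function(object, ...) {
  if (is.null(object$traces)) {
    stop("autoplot.tap_result: run with `record_traces = TRUE`", call. = FALSE)
  }
  df <- tidyr::pivot_longer(object$traces[, c("time", "C1", "C2")],
                            cols = c("C1", "C2"),
                            names_to = "unit", values_to = "activity")
  df$unit <- factor(df$unit, c("C1", "C2"),
                    c("cortex 1 (tap down)", "cortex 2 (lift/shift)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 1000, y = .data$activity)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = object$protocol$action_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~unit, ncol = 1) +
    ggplot2::labs(x = "time [s]", y = "normalised firing rate",
                  title = sprintf("Alternate tapping at D = %.2f: %.2f Hz (%.0f taps/min)",
                                  object$D, object$frequency_hz,
                                  object$frequency_tpm)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a dopamine-to-frequency curve
#'
#' @param object A `d_curve` from [d_to_frequency_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot d_curve
#' @export
autoplot.d_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$D, y = .data$taps_per_min)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "dopaminergic input D", y = "tapping frequency [taps/min]") +
    ggplot2::theme_minimal()
}

#' Plot a simulated levodopa test
#'
#' Three stacked panels over the observation window: plasma and delayed
#' effect-compartment concentration, dopaminergic input, and tapping
#' frequency - the per-patient view of the levodopa kinetic-dynamic test.
#'
#' @param object A `patient_sim` from [simulate_patient()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot patient_sim
#' @export
autoplot.patient_sim <- function(object, ...) {
  rec <- attr(object, "record")
  df <- tibble::tibble(
    time = rep(object$time, 3),
    value = c(object$c1, object$D, object$taps_per_min),
    panel = rep(c("concentration [ug/ml]", "dopaminergic input D",
                  "tapping [taps/min]"), each = nrow(object)),
    series = rep(c("plasma c1", "D", "simulated tapping"), each = nrow(object))
  )
  extra <- tibble::tibble(
    time = object$time, value = object$c3delay,
    panel = "concentration [ug/ml]", series = "effect c3 (delayed)")
  df <- dplyr::bind_rows(df, extra)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time after dose [min]", y = NULL,
                  title = if (!is.null(rec)) paste("Levodopa test:", rec$id) else NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom", legend.title = ggplot2::element_blank())
}
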