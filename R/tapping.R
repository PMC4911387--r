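#' Alternate finger tapping protocol
#'
#' Protocol constants for the simulated alternate tapping task: the trial
#' starts with the tap-down stimulus `S_down = c(1, 0)`; each time a
#' cortical activity crosses `action_threshold` an action (tap down for
#' channel 1, lift/shift for channel 2) is triggered, and after a
#' physiological dead time of `physio_delay` ms the stimulus is reversed so
#' the subject intends the opposite movement.
#'
#' The action threshold is a single calibrated constant, the same at every
#' dopaminergic level.
#'
#' @param action_threshold Cortical activity triggering an action, in
#'   (0.5, 1); "close to the maximum".
#' @param physio_delay Dead time between a selection and the stimulus
#'   reversal \[ms\].
#' @param trial_duration Simulated tapping window \[ms\].
#' @param settle Pre-trial settling time under no stimulus \[ms\].
#' @param dt Euler step \[ms\].
#' @return An object of class `tapping_protocol`.
#' @examples
#' tapping_protocol()
#' @export
tapping_protocol <- function(action_threshold = 0.85, physio_delay = 100,
                             trial_duration = 12000, settle = 1000, dt = 1) {
  if (action_threshold <= 0.5 || action_threshold >= 1) {
    stop("tapping_protocol: `action_threshold` must lie in (0.5, 1)",
         call. = FALSE)
  }
  if (physio_delay < 0) stop("tapping_protocol: `physio_delay` must be >= 0",
                             call. = FALSE)
  if (trial_duration <= 0) stop("tapping_protocol: `trial_duration` must be positive",
                                call. = FALSE)
  structure(list(action_threshold = action_threshold,
                 physio_delay = physio_delay,
                 trial_duration = trial_duration,
                 settle = settle, dt = dt,
                 S_down = c(1, 0), S_up = c(0, 1)),
            class = "tapping_protocol")
}

#' Run the alternate tapping task at a fixed dopaminergic level
#'
#' Simulates the network through the alternate tapping protocol at a
#' constant dopaminergic input D: the tap-down stimulus is presented, each
#' threshold crossing triggers an action and - after the physiological
#' delay - a stimulus reversal, and the recurring alternate pattern of the
#' two cortical units is summarised as a tapping frequency. Frequency
#' counts tap-down (channel 1) events: the mean channel-1 cycle duration
#' after discarding the first (transient) cycle. If fewer than one
#' steady-state cycle completes within the trial the movement is considered
#' blocked and the frequency is zero.
#'
#' @param D Dopaminergic input, >= 0.
#' @param protocol A [tapping_protocol()].
#' @param params A [bg_params()]; set `sigma_noise = 0` for deterministic
#'   runs.
#' @param weights A [bg_weights()].
#' @param clamp_H Clamp the cholinergic interneuron to 0.
#' @param record_traces Keep full activity traces (tibble in the result).
#' @return An object of class `tap_result`: `frequency_hz`,
#'   `frequency_tpm` (= 60 x Hz), `tap_times` (channel-1 crossing times,
#'   ms), `cycle_times` (steady-state channel-1 cycle durations, ms),
#'   `events` (all crossings), `blocked`, plus the call parameters.
#' @examples
#' res <- run_tapping(0.3, tapping_protocol(trial_duration = 6000))
#' res$frequency_hz
#' @export
run_tapping <- function(D, protocol = tapping_protocol(),
                        params = bg_params(), weights = bg_weights(),
                        clamp_H = FALSE, record_traces = FALSE) {
  stopifnot(inherits(protocol, "tapping_protocol"))
  validate_bg_params(params)
  validate_bg_weights(weights)
  if (D < 0) stop("run_tapping: D must be >= 0", call. = FALSE)
  res <- .bg_core(D = D, params = unclass(params), weights = unclass(weights),
                  dt = protocol$dt, settle_ms = protocol$settle,
                  t_max_ms = protocol$trial_duration,
                  threshold = protocol$action_threshold,
                  physio_delay_ms = protocol$physio_delay, mode = 1L,
                  S_init = protocol$S_down, record_traces = record_traces,
                  thin = 1L, clamp_H = clamp_H, init_state = NULL)
  ev <- tibble::tibble(time = res$event_time,
                       channel = as.integer(res$event_channel))
  tap_times <- ev$time[ev$channel == 1L]
  cycles <- if (length(tap_times) >= 2) diff(tap_times) else numeric(0)
  steady <- if (length(cycles) >= 2) cycles[-1] else numeric(0)
  blocked <- length(steady) == 0
  freq_hz <- if (blocked) 0 else 1000 / mean(steady)
  out <- list(
    frequency_hz = freq_hz,
    frequency_tpm = 60 * freq_hz,
    tap_times = tap_times,
    cycle_times = steady,
    events = ev,
    blocked = blocked,
    D = D,
    protocol = protocol
  )
  if (record_traces) out$traces <- traces_tbl(res$traces)
  structure(out, class = "tap_result")
}

#' @export
print.tap_result <- function(x, ...) {
  if (x$blocked) {
    cat("<tap_result>  D =", x$D, " blocked movement (frequency 0)\n")
  } else {
    cat("<tap_result>  D =", x$D, " frequency =",
        round(x$frequency_hz, 2), "Hz (",
        round(x$frequency_tpm), "taps/min ) over",
        length(x$cycle_times), "steady cycles\n")
  }
  invisible(x)
}

#' Tidy the steady-state cycles of a tapping run
#' @param x A `tap_result`.
#' @param ... Unused.
#' @return A tibble with one row per steady-state channel-1 cycle.
#' @method tidy tap_result
#' @export
tidy.tap_result <- function(x, ...) {
  n <- length(x$cycle_times)
  tibble::tibble(
    cycle = seq_len(n),
    start = x$tap_times[seq_len(n) + 1L],
    duration_ms = x$cycle_times
  )
}

#' One-row summary of a tapping run
#' @param x A `tap_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance tap_result
#' @export
glance.tap_result <- function(x, ...) {
  tibble::tibble(
    D = x$D,
    frequency_hz = x$frequency_hz,
    taps_per_min = x$frequency_tpm,
    n_taps = length(x$tap_times),
    blocked = x$blocked
  )
}

#' Dopamine-to-frequency curve
#'
#' Evaluates the tapping simulation over a grid of dopaminergic inputs,
#' each point computed independently (the curve is invariant to grid
#' ordering and refinement). The curve rises monotonically with D and
#' saturates at high D: small dopamine fluctuations barely move a healthy
#' subject, while the steep low-D region is where parkinsonian bradykinesia
#' fluctuates most.
#'
#' @param d_grid Increasing dopaminergic input values in \[0, 1\].
#' @param protocol A [tapping_protocol()].
#' @param params,weights Network configuration, see [run_tapping()].
#' @return A tibble of class `d_curve` with columns `D`, `frequency_hz`,
#'   `taps_per_min`.
#' @examples
#' curve <- d_to_frequency_curve(c(0.2, 0.4), tapping_protocol(trial_duration = 6000))
#' curve
#' @export
d_to_frequency_curve <- function(d_grid, protocol = tapping_protocol(),
                                 params = bg_params(),
                                 weights = bg_weights()) {
  if (any(d_grid < 0 | d_grid > 1)) {
    stop("d_to_frequency_curve: grid must lie within [0, 1]", call. = FALSE)
  }
  rows <- purrr::map(sort(d_grid), function(D) {
    glance(run_tapping(D, protocol, params, weights))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select(D, frequency_hz, taps_per_min)
  class(out) <- c("d_curve", class(out))
  out
}

#' Interpolate a precomputed dopamine-to-frequency curve
#'
#' Monotone piecewise-linear interpolation of a [d_to_frequency_curve()]
#' result; exact at grid points. Out-of-range inputs are clamped to the end
#' values with a message.
#'
#' @param curve A `d_curve` tibble.
#' @param D Dopaminergic input value(s).
#' @return Tapping frequency in taps/min.
#' @export
frequency_lookup <- function(curve, D) {
  if (!all(c("D", "taps_per_min") %in% names(curve))) {
    stop("frequency_lookup: `curve` must have `D` and `taps_per_min` columns",
         call. = FALSE)
  }
  if (any(D < min(curve$D) | D > max(curve$D))) {
    message("frequency_lookup: D outside curve range [",
            min(curve$D), ", ", max(curve$D), "]; clamping to end values")
  }
  stats::approx(curve$D, curve$taps_per_min, xout = D, method = "linear",
                rule = 2)$y
}
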