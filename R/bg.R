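#' Static neuron activation
#'
#' Logistic input-output relationship of every model neuron,
#' `1 / (1 + exp(-a (u - u0)))`: a lower threshold and an upper saturation,
#' output strictly in (0, 1).
#'
#' @param u Net input(s); vectorised.
#' @param params A [bg_params()] (uses `a` and `u0`).
#' @return Activation value(s) in (0, 1).
#' @examples
#' unit_response(c(0, 1, 1.5), bg_params())
#' @export
unit_response <- function(u, params = bg_params()) {
  1 / (1 + exp(-params$a * (u - params$u0)))
}

#' Dopaminergic and cholinergic modulation terms
#'
#' Computes the additive input terms through which the dopaminergic input D
#' modulates the striatum: a contrast-enhancing term on Go neurons
#' (`+alpha*D` for channels whose sensory-related drive exceeds `theta_G`,
#' `-alpha*D` otherwise), a uniform inhibitory term `beta*D` on NoGo
#' neurons, and an inhibitory term `gamma*D` on the cholinergic
#' interneuron. The cholinergic activity in turn reaches the striatum with
#' weights `w_GH` (inhibits Go) and `w_NH` (excites NoGo); see
#' [step_network()].
#'
#' The contrast gate operates on the sensory-related drive of each Go unit
#' (`W_GS * S_i`), not on its output activity: dopamine boosts the Go
#' neurons of the stimulus-preferred channel and depresses the others.
#'
#' @param D Dopaminergic input, >= 0.
#' @param go_drive Per-channel sensory-related Go drive (`W_GS * S`).
#' @param params A [bg_params()].
#' @return A list with components `go` (per channel), `nogo`, `chi`.
#' @examples
#' dopamine_drive(0.55, go_drive = c(0.9, 0), params = bg_params())
#' @export
dopamine_drive <- function(D, go_drive, params = bg_params()) {
  if (D < 0) stop("dopamine_drive: D must be >= 0", call. = FALSE)
  list(
    go = ifelse(go_drive > params$theta_G, params$alpha * D, -params$alpha * D),
    nogo = params$beta * D,
    chi = params$gamma * D
  )
}

bg_state_names <- function() {
  c("C1", "C2", "G1", "G2", "N1", "N2", "E1", "E2",
    "I1", "I2", "T1", "T2", "STN", "H")
}

#' Network state at rest
#'
#' @param values Optional named numeric vector overriding individual
#'   activities (all zero by default).
#' @return A named numeric state vector (activities of cortex, Go, NoGo,
#'   GPe, GPi, thalamus per channel, plus STN and the cholinergic
#'   interneuron), each in \[0, 1\].
#' @examples
#' bg_state(c(H = 0.5))
#' @export
bg_state <- function(values = NULL) {
  s <- stats::setNames(numeric(14), bg_state_names())
  if (!is.null(values)) {
    bad <- setdiff(names(values), names(s))
    if (length(bad)) stop("bg_state: unknown state name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    s[names(values)] <- values
  }
  if (any(s < 0 | s > 1)) {
    stop("bg_state: activities must lie in [0, 1]", call. = FALSE)
  }
  s
}

#' Advance the network by one Euler step
#'
#' Reference (pure R) implementation of one explicit Euler step of the
#' network dynamics: every population obeys
#' `tau * dz/dt = -z + unit_response(u)` with the net inputs given by the
#' wiring of the model (cortex with lateral inhibition and thalamic
#' feedback; striatal Go/NoGo under dopaminergic and cholinergic
#' modulation; GPe/GPi with tonic drives; thalamus gated by GPi; a shared
#' subthalamic stop unit driven by stimulus-cortex conflict whose release
#' follows the slow time constant `tau_L`; a shared cholinergic
#' interneuron inhibited by dopamine). The compiled simulator used by
#' [run_tapping()] and [simulate_selection()] advances the same equations;
#' the two routes are cross-checked in the package tests.
#'
#' @param state A state vector from [bg_state()].
#' @param S Sensory input vector, length 2.
#' @param D Dopaminergic input.
#' @param dt Step \[ms\]; must satisfy `dt <= tau / 10`... practical
#'   stability of the explicit scheme (default 1 ms).
#' @param params A [bg_params()].
#' @param weights A [bg_weights()].
#' @param clamp_H Clamp the cholinergic interneuron to 0 (lesion study).
#' @return The state vector after one step.
#' @examples
#' s <- bg_state()
#' step_network(s, S = c(1, 0), D = 0.55)
#' @export
step_network <- function(state, S, D, dt = 1, params = bg_params(),
                         weights = bg_weights(), clamp_H = FALSE) {
  if (dt > params$tau / 10) {
    stop("step_network: require dt <= tau/10 for the explicit scheme",
         call. = FALSE)
  }
  z <- state
  w <- weights
  Hval <- if (clamp_H) 0 else z[["H"]]
  dop <- dopamine_drive(D, go_drive = w$W_GS * S, params)
  conflict <- S[1] * z[["C2"]] + S[2] * z[["C1"]]

  u <- c(
    C1 = w$W_CS_diag * S[1] + w$W_CS_off * S[2] + w$W_CT * z[["T1"]] + w$L * z[["C2"]],
    C2 = w$W_CS_diag * S[2] + w$W_CS_off * S[1] + w$W_CT * z[["T2"]] + w$L * z[["C1"]],
    G1 = w$W_GC * z[["C1"]] + w$W_GS * S[1] + dop$go[1] + w$w_GH * Hval,
    G2 = w$W_GC * z[["C2"]] + w$W_GS * S[2] + dop$go[2] + w$w_GH * Hval,
    N1 = w$W_NC * z[["C1"]] + w$W_NS * S[1] + dop$nogo + w$w_NH * Hval,
    N2 = w$W_NC * z[["C2"]] + w$W_NS * S[2] + dop$nogo + w$w_NH * Hval,
    E1 = params$I_E + w$W_EN * z[["N1"]] + w$w_ESTN * z[["STN"]],
    E2 = params$I_E + w$W_EN * z[["N2"]] + w$w_ESTN * z[["STN"]],
    I1 = params$I_I + w$W_IG * z[["G1"]] + w$W_IE * z[["E1"]] + w$w_ISTN * z[["STN"]],
    I2 = params$I_I + w$W_IG * z[["G2"]] + w$W_IE * z[["E2"]] + w$w_ISTN * z[["STN"]],
    T1 = w$W_TC * z[["C1"]] + w$W_TI * z[["I1"]],
    T2 = w$W_TC * z[["C2"]] + w$W_TI * z[["I2"]],
    STN = w$k_E * conflict + w$W_STNE * (z[["E1"]] + z[["E2"]]),
    H = params$I_H + params$gamma * D
  )
  target <- unit_response(u, params)
  tc <- rep(params$tau, 14)
  if (target[["STN"]] < z[["STN"]]) tc[13] <- params$tau_L
  z_new <- z + dt / tc * (-z + target)
  pmin(pmax(z_new, 0), 1)
}

#' Simulate action selection under a fixed stimulus
#'
#' Integrates the network from an initial state under a constant sensory
#' input until the first cortical activity crosses the action threshold
#' (linear interpolation between steps), or until `max_time` elapses.
#' A timeout is returned as an explicit no-selection result, representing
#' fully blocked movement at very low dopaminergic input.
#'
#' @param S Sensory input vector, length 2.
#' @param D Dopaminergic input.
#' @param threshold Action threshold on cortical activity, in (0.5, 1).
#' @param max_time Maximum simulated time \[ms\].
#' @param params A [bg_params()]; acceptance-style runs use
#'   `sigma_noise = 0`.
#' @param weights A [bg_weights()].
#' @param initial Optional initial state from [bg_state()]; defaults to
#'   rest (zeros) settled for `settle` ms under no stimulus.
#' @param dt Euler step \[ms\].
#' @param settle Pre-stimulus settling time \[ms\].
#' @param clamp_H Clamp the cholinergic interneuron to 0.
#' @param record_traces Keep full activity traces.
#' @return A list of class `bg_selection`: `selected` (logical),
#'   `selection_time` \[ms\] (NA on timeout), `winner` (1, 2 or NA), and a
#'   `traces` tibble when requested.
#' @examples
#' sel <- simulate_selection(c(1, 0), D = 0.55)
#' sel$selection_time
#' @export
simulate_selection <- function(S, D, threshold = 0.85, max_time = 10000,
                               params = bg_params(), weights = bg_weights(),
                               initial = NULL, dt = 1, settle = 1000,
                               clamp_H = FALSE, record_traces = FALSE) {
  validate_bg_params(params)
  validate_bg_weights(weights)
  if (threshold <= 0.5 || threshold >= 1) {
    stop("simulate_selection: `threshold` must lie in (0.5, 1)", call. = FALSE)
  }
  res <- .bg_core(D = D, params = unclass(params), weights = unclass(weights),
                  dt = dt, settle_ms = settle, t_max_ms = max_time,
                  threshold = threshold, physio_delay_ms = 0, mode = 0L,
                  S_init = as.numeric(S), record_traces = record_traces,
                  thin = 1L, clamp_H = clamp_H, init_state = initial)
  selected <- length(res$event_time) > 0
  out <- list(
    selected = selected,
    selection_time = if (selected) res$event_time[1] else NA_real_,
    winner = if (selected) as.integer(res$event_channel[1]) else NA_integer_,
    timed_out = !selected,
    final_state = stats::setNames(res$final_state, bg_state_names()),
    D = D, threshold = threshold
  )
  if (record_traces) out$traces <- traces_tbl(res$traces)
  structure(out, class = "bg_selection")
}

traces_tbl <- function(m) {
  colnames(m) <- c("time", bg_state_names())
  tibble::as_tibble(as.data.frame(m))
}

#' @export
print.bg_selection <- function(x, ...) {
  if (x$selected) {
    cat("<bg_selection>  channel", x$winner, "selected at",
        round(x$selection_time, 1), "ms  (D =", x$D,
        ", threshold =", x$threshold, ")\n")
  } else {
    cat("<bg_selection>  no selection (timeout)  (D =", x$D, ")\n")
  }
  invisible(x)
}
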