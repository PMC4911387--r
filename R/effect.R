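#' Simulate the brain effect compartment
#'
#' Integrates the one-way effect compartment
#' \deqn{\dot c_3 = (k_{31}/V_3)\, c_1(t) - (k_{e3}/V_3)\, c_3,\qquad c_3(0)=0,}
#' driven by the linearly interpolated plasma concentration, using an exact
#' exponential integrator (closed-form update per sampling interval). No
#' levodopa returns from the effect compartment to plasma, so the coupling
#' is strictly one-way. In steady state \eqn{c_3 \to (k_{31}/k_{e3})\, c_1}.
#'
#' @param c1 Data frame with `time` \[min\] and `value` \[µg/ml\] (plasma
#'   concentration), sampled densely enough for interpolation. A tibble
#'   from [simulate_plasma()] is accepted directly (its `c1` column is
#'   used).
#' @param params An [effect_params()].
#' @return A tibble with columns `time` and `value` (`c3`, µg/ml) on the
#'   same grid as `c1`.
#' @examples
#' p <- effect_params(ke3_over_V3 = 0.02, T_delay = 0, D0 = 0.28,
#'                    Dmax = 0.317, Dc50 = 0.03, N = 2)
#' c1 <- ts_series(seq(0, 240, 5), pmin(seq(0, 240, 5) / 60, 1.2),
#'                 unit = "ug/ml")
#' tail(simulate_effect(c1, p))
#' @export
simulate_effect <- function(c1, params) {
  validate_effect_params(params)
  c1 <- as_c1_series(c1)
  assert_ts(c1, "c1", non_negative = TRUE)
  tt <- c1$time
  vv <- c1$value
  k <- params$ke3_over_V3
  # exact exponential integrator: with c1 linear on each sampling interval
  # the solution of the linear ODE has a closed-form update, so the result
  # is machine-precision accurate for the interpolated input and exactly
  # proportional to k31/V3 (the rescaling argument holds to float precision)
  n <- length(tt)
  c3 <- numeric(n)
  if (n > 1) {
    h <- diff(tt)
    slope <- diff(vv) / h
    ekh <- exp(-k * h)
    g1 <- (1 - ekh) / k          # int e^{-k(h-s)} ds
    g2 <- (h - g1) / k           # int s e^{-k(h-s)} ds
    for (i in seq_len(n - 1)) {
      c3[i + 1] <- c3[i] * ekh[i] +
        params$k31_over_V3 * (vv[i] * g1[i] + slope[i] * g2[i])
    }
  }
  out <- tibble::tibble(time = tt, value = pmax(c3, 0))
  attr(out, "unit") <- "ug/ml"
  out
}

# accept either a (time, value) series or a simulate_plasma() result
as_c1_series <- function(x) {
  if (is.data.frame(x) && "c1" %in% names(x) && !"value" %in% names(x)) {
    out <- tibble::tibble(time = x$time, value = x$c1)
    attr(out, "unit") <- "ug/ml"
    return(out)
  }
  x
}

#' Apply a pure transport delay to a series
#'
#' Returns the series shifted by `T_delay`: the value at time `t` equals the
#' input at `t - T_delay`, with linear interpolation between samples; values
#' before the delay has elapsed equal the initial value of the input (zero
#' for a drug-free start).
#'
#' @param x Data frame with `time` and `value` columns.
#' @param T_delay Delay \[min\], >= 0.
#' @return A tibble on the same time grid with delayed values.
#' @examples
#' ramp <- ts_series(0:10, 0:10)
#' delay_series(ramp, 3)
#' @export
delay_series <- function(x, T_delay) {
  assert_ts(x, "series")
  if (T_delay < 0) stop("delay_series: `T_delay` must be >= 0", call. = FALSE)
  if (T_delay == 0) return(tibble::as_tibble(x[, c("time", "value")]))
  shifted <- x$time - T_delay
  v <- stats::approx(x$time, x$value, xout = shifted, method = "linear",
                     yleft = x$value[1], yright = x$value[nrow(x)])$y
  out <- tibble::tibble(time = x$time, value = v)
  attr(out, "unit") <- ts_unit(x)
  out
}

#' Hill concentration-effect law
#'
#' Converts a delayed effect-compartment concentration into the
#' dimensionless dopaminergic input
#' \deqn{D = D_0 + D_{max} \frac{c^N}{D_{c50}^N + c^N}.}
#' `D0` is the basal (pre-dose) level; the drug term saturates at `Dmax`
#' with half-maximum at `Dc50` and steepness set by the Hill coefficient
#' `N` (slope at `Dc50` equals `N * Dmax / (4 * Dc50)`).
#'
#' @param c3delay Delayed effect-compartment concentration(s) \[µg/ml\],
#'   >= 0; vectorised.
#' @param params An [effect_params()].
#' @return Dopaminergic input value(s) in `[D0, D0 + Dmax)`.
#' @examples
#' p <- effect_params(0.02, 0, D0 = 0.28, Dmax = 0.317, Dc50 = 0.03, N = 2)
#' hill_effect(c(0, 0.03, 10), p)
#' @export
hill_effect <- function(c3delay, params) {
  validate_effect_params(params)
  if (any(c3delay < 0)) {
    stop("hill_effect: concentration must be non-negative", call. = FALSE)
  }
  cn <- c3delay^params$N
  params$D0 + params$Dmax * cn / (params$Dc50^params$N + cn)
}

#' Full plasma-to-dopamine effect chain
#'
#' Composes [simulate_effect()], [delay_series()] and [hill_effect()]:
#' plasma concentration to effect-compartment concentration, pure delay
#' `T`, then the Hill law. The result is the dopaminergic input handed to
#' the basal ganglia network.
#'
#' @inheritParams simulate_effect
#' @return A tibble with columns `time`, `c3`, `c3delay` and `D`.
#' @examples
#' p <- effect_params(0.02, 15, D0 = 0.28, Dmax = 0.317, Dc50 = 0.03, N = 2)
#' c1 <- ts_series(seq(0, 240, 5), pmin(seq(0, 240, 5) / 60, 1.2),
#'                 unit = "ug/ml")
#' tail(effect_chain(c1, p))
#' @export
effect_chain <- function(c1, params) {
  c1 <- as_c1_series(c1)
  c3 <- simulate_effect(c1, params)
  c3d <- delay_series(c3, params$T_delay)
  tibble::tibble(
    time = c3$time,
    c3 = c3$value,
    c3delay = c3d$value,
    D = hill_effect(c3d$value, params)
  )
}
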