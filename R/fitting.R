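#' Grid specification for effect-parameter search
#'
#' Defines per-parameter candidate values for the mechanised stand-in for
#' manual tuning of the effect/Hill constants. The Hill coefficient is
#' restricted to integers >= 1, matching how it is reported clinically.
#'
#' @param ke3_over_V3,T_delay,D0,Dmax,Dc50,N Numeric vectors of candidate
#'   values (each may be length 1 to pin a parameter).
#' @param loss `"squared"` (sum of squared taps/min residuals) or
#'   `"huber"` (robust; resists tapping outliers).
#' @param huber_delta Huber transition point \[taps/min\].
#' @return An object of class `effect_grid`.
#' @examples
#' effect_grid(ke3_over_V3 = c(0.01, 0.02), T_delay = 0, D0 = 0.28,
#'             Dmax = 0.317, Dc50 = c(0.03, 0.1), N = c(2, 8))
#' @export
effect_grid <- function(ke3_over_V3, T_delay = c(0, 15), D0, Dmax, Dc50, N,
                        loss = c("squared", "huber"), huber_delta = 10) {
  loss <- match.arg(loss)
  if (any(N != round(N)) || any(N < 1)) {
    stop("effect_grid: `N` must contain integers >= 1", call. = FALSE)
  }
  g <- list(ke3_over_V3 = ke3_over_V3, T_delay = T_delay, D0 = D0,
            Dmax = Dmax, Dc50 = Dc50, N = N)
  if (any(lengths(g) == 0)) stop("effect_grid: empty parameter list", call. = FALSE)
  structure(list(grid = g, loss = loss, huber_delta = huber_delta),
            class = "effect_grid")
}

huber_rho <- function(r, delta) {
  a <- abs(r)
  ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta))
}

#' Grid search for effect/Hill parameters
#'
#' Exhaustively evaluates every parameter combination of an
#' [effect_grid()] against an observed tapping-frequency series: each
#' candidate is run through [effect_chain()] on the supplied plasma curve
#' and converted to taps/min through the dopamine-to-frequency curve, and
#' the loss against the observations is recorded. The ranking is
#' deterministic and invariant to grid ordering. The full loss surface is
#' returned so that near-equivalent parameter combinations are visible
#' rather than hidden behind a single point estimate.
#'
#' @param observed_tapping Data frame with `time` \[min\] and `value` (or
#'   `taps_per_min`) columns.
#' @param c1 Plasma concentration series (`time`, `value`), e.g. from
#'   [simulate_plasma()].
#' @param grid An [effect_grid()].
#' @param curve A precomputed [d_to_frequency_curve()] result used for the
#'   dopamine-to-frequency conversion.
#' @param k31_over_V3 Fixed absorption ratio used for all candidates.
#' @return A tibble of class `effect_fit` with one row per candidate,
#'   sorted by loss (ties broken by parameter values); attribute `best`
#'   holds the top candidate as an [effect_params()].
#' @export
grid_fit_effect <- function(observed_tapping, c1, grid, curve,
                            k31_over_V3 = 0.01) {
  stopifnot(inherits(grid, "effect_grid"))
  if ("taps_per_min" %in% names(observed_tapping) &&
      !"value" %in% names(observed_tapping)) {
    observed_tapping <- dplyr::rename(observed_tapping, value = "taps_per_min")
  }
  assert_ts(observed_tapping, "observed_tapping")
  c1 <- as_c1_series(c1)
  assert_ts(c1, "c1", non_negative = TRUE)
  if (max(observed_tapping$time) > max(c1$time)) {
    stop("grid_fit_effect: plasma series does not cover the tapping horizon",
         call. = FALSE)
  }

  cand <- tidyr::expand_grid(!!!grid$grid)
  if (!nrow(cand)) stop("grid_fit_effect: empty grid", call. = FALSE)

  obs_t <- observed_tapping$time
  obs_v <- observed_tapping$value

  loss_one <- function(ke3_over_V3_i, T_delay, D0, Dmax, Dc50, N) {
    p <- tryCatch(
      effect_params(ke3_over_V3 = ke3_over_V3_i, T_delay = T_delay, D0 = D0,
                    Dmax = Dmax, Dc50 = Dc50, N = N,
                    k31_over_V3 = k31_over_V3),
      error = function(e) NULL)
    if (is.null(p)) return(NA_real_)
    ch <- effect_chain(c1, p)
    D_obs <- stats::approx(ch$time, ch$D, xout = obs_t, rule = 2)$y
    pred <- frequency_lookup(curve, D_obs)
    r <- pred - obs_v
    if (grid$loss == "squared") sum(r^2) else sum(huber_rho(r, grid$huber_delta))
  }

  cand$loss <- purrr::pmap_dbl(cand, function(ke3_over_V3, T_delay, D0,
                                              Dmax, Dc50, N) {
    loss_one(ke3_over_V3, T_delay, D0, Dmax, Dc50, N)
  })
  out <- dplyr::arrange(cand, loss, ke3_over_V3, T_delay, D0, Dmax, Dc50, N)
  best <- out[1, ]
  attr(out, "best") <- effect_params(
    ke3_over_V3 = best$ke3_over_V3, T_delay = best$T_delay, D0 = best$D0,
    Dmax = best$Dmax, Dc50 = best$Dc50, N = best$N,
    k31_over_V3 = k31_over_V3)
  attr(out, "loss") <- grid$loss
  class(out) <- c("effect_fit", class(out))
  out
}
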