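# Shared fixtures. The dopamine-to-frequency curve is expensive enough to be
# worth caching across test files; everything else is built in place.

default_prot <- function(trial = 15000) {
  tapping_protocol(trial_duration = trial)
}

.fixture_env <- new.env(parent = emptyenv())

curve_fixture <- function() {
  if (is.null(.fixture_env$curve)) {
    .fixture_env$curve <- d_to_frequency_curve(
      seq(0.05, 0.8, by = 0.025), default_prot())
  }
  .fixture_env$curve
}

# Independent matrix-exponential solution of the linear plasma system,
# piecewise over the absorption-window segments (oracle for simulate_plasma).
matexp_plasma <- function(params, schedule, times) {
  A <- matrix(c(-(params$k21 + params$ketot) / params$V1, params$k12 / params$V1,
                params$k21 / params$V2, -params$k12 / params$V2),
              2, 2, byrow = TRUE)
  rate <- schedule$dose_ug / 1000 / schedule$duration_min
  w0 <- schedule$t_start_min; w1 <- w0 + schedule$duration_min
  edges <- c(0, w0, w1)
  bs <- list(c(0, 0), c(rate / params$V1, 0), c(0, 0))
  x_edge <- list(c(0, 0))
  prop <- function(x0, b, h) {
    E <- as.matrix(Matrix::expm(A * h))
    if (all(b == 0)) as.numeric(E %*% x0)
    else {
      xp <- -solve(A, b)
      as.numeric(E %*% (x0 - xp) + xp)
    }
  }
  for (k in 2:3) x_edge[[k]] <- prop(x_edge[[k - 1]], bs[[k - 1]],
                                     edges[k] - edges[k - 1])
  t(vapply(times, function(t) {
    seg <- findInterval(t, edges)
    prop(x_edge[[seg]], bs[[seg]], t - edges[seg])
  }, numeric(2)))
}

# random smooth non-negative plasma-like trace on [0, 240]
random_trace <- function(seed, n = 97) {
  set.seed(seed)
  tt <- seq(0, 240, length.out = n)
  peak_t <- runif(1, 20, 60)
  amp <- runif(1, 0.5, 2.5)
  decay <- runif(1, 0.01, 0.04)
  v <- amp * pmax(tt, 0) / peak_t * exp(1 - tt / peak_t) +
    0.2 * amp * exp(-decay * tt) * sin(tt / 40)^2
  ts_series(tt, pmax(v, 0), unit = "ug/ml")
}

# brute-force quadrature of the effect-compartment convolution integral
# (dense trapezoid; independent of the package's exponential integrator)
convolution_c3 <- function(c1, params, t_eval) {
  f <- stats::approxfun(c1$time, c1$value, rule = 2)
  k31 <- params$k31_over_V3; ke3 <- params$ke3_over_V3
  vapply(t_eval, function(t) {
    if (t == 0) return(0)
    tau <- seq(0, t, length.out = 20001L)
    g <- f(tau) * exp(-ke3 * (t - tau))
    h <- tau[2] - tau[1]
    k31 * h * (sum(g) - (g[1] + g[length(g)]) / 2)
  }, numeric(1))
}

freq_at <- function(curve, D) curve$frequency_hz[abs(curve$D - D) < 1e-9][1]
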