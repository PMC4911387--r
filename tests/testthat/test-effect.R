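eff <- effect_params(ke3_over_V3 = 0.02, T_delay = 0, D0 = 0.28,
                     Dmax = 0.317, Dc50 = 0.03, N = 2)

test_that("effect compartment: zero input and steady-state proportionality", {
  z <- ts_series(seq(0, 240, 5), rep(0, 49), unit = "ug/ml")
  expect_true(all(simulate_effect(z, eff)$value == 0))
  # constant plasma held long enough: c3 -> (k31/ke3) * C
  C <- 1.4
  long <- ts_series(seq(0, 2000, 5), rep(C, 401), unit = "ug/ml")
  c3 <- simulate_effect(long, eff)
  gain <- eff$k31_over_V3 / eff$ke3_over_V3
  expect_equal(tail(c3$value, 1), gain * C, tolerance = 1e-6)
})

test_that("ODE route matches direct quadrature of the convolution integral", {
  for (seed in 1:20) {
    tr <- random_trace(seed)
    p <- effect_params(ke3_over_V3 = runif(1, 0.008, 0.04), T_delay = 0,
                       D0 = 0.25, Dmax = 0.3, Dc50 = 0.1, N = 2)
    c3 <- simulate_effect(tr, p)
    t_eval <- c(30, 60, 120, 180, 240)
    orc <- convolution_c3(tr, p, t_eval)
    got <- c3$value[match(t_eval, c3$time)]
    expect_lt(max(abs(got - orc) / pmax(abs(orc), 1e-10)), 1e-4)
  }
})

test_that("pure delay: identity, ramp shift and off-grid interpolation", {
  ramp <- ts_series(0:240, 0:240)
  expect_equal(delay_series(ramp, 0)$value, ramp$value)
  d15 <- delay_series(ramp, 15)
  expect_equal(d15$value[d15$time >= 15], d15$time[d15$time >= 15] - 15)
  expect_true(all(d15$value[d15$time < 15] == 0))
  # off-grid delay on a piecewise-linear trace against analytic shift
  tt <- seq(0, 100, by = 2.5)
  f <- function(t) pmax(0, pmin(t / 20, 1)) * exp(-t / 80)
  pl <- ts_series(tt, f(tt))
  d <- delay_series(pl, 7.5)
  # 7.5 is a multiple of the 2.5 min grid, so the shift is exact
  oracle <- c(rep(pl$value[1], 3), pl$value[1:(length(tt) - 3)])
  expect_lt(max(abs(d$value - oracle)), 1e-9)
})

test_that("Hill law closed forms and monotonicity", {
  expect_equal(hill_effect(0, eff), eff$D0)
  expect_equal(hill_effect(eff$Dc50, eff), eff$D0 + eff$Dmax / 2)
  # group 1 subject 2 constants at c = Dc50
  expect_equal(hill_effect(0.03, eff), 0.4385, tolerance = 1e-10)
  cc <- seq(0, 1, by = 0.001)
  expect_true(all(diff(hill_effect(cc, eff)) > 0))
  expect_true(all(hill_effect(cc, eff) >= eff$D0 &
                    hill_effect(cc, eff) < eff$D0 + eff$Dmax))
  expect_error(hill_effect(-0.1, eff), "non-negative")
})

test_that("Hill slope at Dc50 equals N * Dmax / (4 * Dc50)", {
  for (N in c(2, 5, 8)) {
    p <- effect_params(0.02, 0, D0 = 0.25, Dmax = 0.3, Dc50 = 0.12, N = N)
    h <- 1e-6
    slope <- (hill_effect(p$Dc50 + h, p) - hill_effect(p$Dc50 - h, p)) / (2 * h)
    expect_equal(slope, N * p$Dmax / (4 * p$Dc50), tolerance = 1e-6)
  }
  # larger N steepens the curve at Dc50
  s_of <- function(N) {
    p <- effect_params(0.02, 0, 0.25, 0.3, 0.12, N)
    (hill_effect(0.12 + 1e-6, p) - hill_effect(0.12 - 1e-6, p)) / 2e-6
  }
  expect_true(s_of(8) > s_of(2))
})

test_that("effect chain: basal input for zero plasma, bounds everywhere", {
  z <- ts_series(seq(0, 240, 5), rep(0, 49), unit = "ug/ml")
  ch <- effect_chain(z, eff)
  expect_true(all(ch$D == eff$D0))
  tr <- random_trace(3)
  ch2 <- effect_chain(tr, eff)
  expect_true(all(ch2$D >= eff$D0 & ch2$D < eff$D0 + eff$Dmax))
})

test_that("joint rescaling of k31/V3 and Dc50 leaves D(t) unchanged", {
  tr <- random_trace(11)
  for (lambda in c(0.1, 10, 137)) {
    p1 <- effect_params(0.02, 15, 0.28, 0.317, 0.03, 2, k31_over_V3 = 0.01)
    p2 <- effect_params(0.02, 15, 0.28, 0.317, 0.03 * lambda, 2,
                        k31_over_V3 = 0.01 * lambda)
    D1 <- effect_chain(tr, p1)$D
    D2 <- effect_chain(tr, p2)$D
    expect_lt(max(abs(D1 - D2)), 1e-10)
  }
})

test_that("large Hill coefficient approaches a delayed switch", {
  tt <- seq(0, 400, by = 2)
  step <- ts_series(tt, ifelse(tt >= 50, 1.2, 0), unit = "ug/ml")
  p <- effect_params(ke3_over_V3 = 0.02, T_delay = 20, D0 = 0.2,
                     Dmax = 0.4, Dc50 = 0.3, N = 60)
  ch <- effect_chain(step, p)
  # threshold crossing of the (delayed) effect concentration
  cross <- ch$time[which(ch$c3delay >= p$Dc50)[1]]
  before <- ch$D[ch$time < cross - 10]
  after <- ch$D[ch$time > cross + 10]
  expect_true(all(abs(before - p$D0) < 0.01))
  expect_true(all(abs(after - (p$D0 + p$Dmax)) < 0.01))
})

test_that("effect parameter validation enforces the model's constraints", {
  expect_error(effect_params(0, 0, 0.28, 0.3, 0.1, 2), "positive")
  expect_error(effect_params(0.02, -1, 0.28, 0.3, 0.1, 2), "T_delay")
  expect_error(effect_params(0.02, 0, 0.28, 0.3, 0.1, 0.5), "Hill")
  expect_error(effect_params(0.02, 0, 0.6, 0.5, 0.1, 2), "D0")
})
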