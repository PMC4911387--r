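quiet_bg <- function() bg_params(sigma_noise = 0)

test_that("unit response has midpoint, saturation and known values", {
  p <- bg_params()
  expect_equal(unit_response(p$u0, p), 0.5)
  expect_equal(unit_response(1e3, p), 1)
  expect_equal(unit_response(-1e3, p), 0)
  expect_equal(unit_response(1.5, p), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(round(unit_response(1.5, p), 4), 0.8808)
  u <- seq(-3, 5, by = 0.01)
  expect_true(all(diff(unit_response(u, p)) > 0))
})

test_that("dopamine modulation terms follow the sign rules", {
  p <- bg_params()
  d0 <- dopamine_drive(0, go_drive = c(0.9, 0), p)
  expect_equal(unlist(d0), c(go1 = 0, go2 = 0, nogo = 0, chi = 0),
               ignore_attr = TRUE)
  d <- dopamine_drive(0.55, go_drive = c(0.9, 0), p)
  expect_equal(d$go, c(0.55, -0.55))   # contrast enhancement around theta_G
  expect_equal(d$nogo, -0.55)          # beta = -1: inhibitory on NoGo
  expect_equal(d$chi, -0.55)           # gamma = -1: inhibitory on ChI
  expect_error(dopamine_drive(-0.1, c(0, 0), p), ">= 0")
})

test_that("R reference step and compiled core advance identical trajectories", {
  p <- quiet_bg(); w <- bg_weights()
  for (cfg in list(list(S = c(1, 0), D = 0.05),
                   list(S = c(0, 0), D = 0.55))) {
    n <- 400
    res <- levotap:::.bg_core(D = cfg$D, params = unclass(p),
                              weights = unclass(w), dt = 1, settle_ms = 0,
                              t_max_ms = n, threshold = 0.9999999,
                              physio_delay_ms = 0, mode = 0L,
                              S_init = cfg$S, record_traces = TRUE, thin = 1L,
                              clamp_H = FALSE, init_state = NULL)
    z <- bg_state()
    for (k in seq_len(n)) {
      z <- step_network(z, S = cfg$S, D = cfg$D, dt = 1, params = p, weights = w)
    }
    cpp_final <- res$final_state
    expect_lt(max(abs(z - cpp_final)), 1e-12)
  }
})

test_that("all activities stay within [0, 1] under varied inputs", {
  p <- quiet_bg(); w <- bg_weights()
  for (cfg in list(c(0, 0, 0), c(1, 0, 0.55), c(1, 1, 0.9), c(0, 1, 0.22))) {
    res <- levotap:::.bg_core(D = cfg[3], params = unclass(p),
                              weights = unclass(w), dt = 1, settle_ms = 0,
                              t_max_ms = 2000, threshold = 0.9999999,
                              physio_delay_ms = 0, mode = 0L,
                              S_init = cfg[1:2], record_traces = TRUE,
                              thin = 1L, clamp_H = FALSE, init_state = NULL)
    tr <- as.matrix(res$traces)[, -1]
    expect_true(all(tr >= 0 & tr <= 1))
  }
})

test_that("without stimulus the thalamus is suppressed and no action starts", {
  sel <- simulate_selection(c(0, 0), D = 0, threshold = 0.9, max_time = 3000)
  expect_false(sel$selected)
  expect_true(sel$timed_out)
  expect_lt(sel$final_state[["T1"]], 0.1)
  expect_lt(sel$final_state[["T2"]], 0.1)
})

test_that("winner-takes-all: stimulated channel wins, rival suppressed", {
  sel <- simulate_selection(c(1, 0), D = 0.55, threshold = 0.995,
                            max_time = 4000, record_traces = TRUE)
  expect_true(sel$selected)
  expect_equal(sel$winner, 1L)
  # exclusivity at the crossing: exactly one cortical unit above threshold
  at_cross <- sel$traces[which(sel$traces$time >= sel$selection_time)[1], ]
  expect_lt(at_cross$C2, sel$threshold)
  # winner converges toward 1 while the rival is laterally suppressed
  last <- sel$final_state
  expect_gt(last[["C1"]], 0.99)
  expect_lt(last[["C2"]], 0.05)
})

test_that("selection time shortens with dopaminergic input", {
  Ds <- seq(0.15, 0.55, by = 0.05)
  st <- vapply(Ds, function(D) {
    simulate_selection(c(1, 0), D, threshold = 0.9)$selection_time
  }, numeric(1))
  expect_true(all(is.finite(st)))
  # non-increasing up to the Euler/event-interpolation resolution (ms scale)
  expect_true(all(diff(st) <= 3))
  expect_gt(st[1], st[length(st)])
})

test_that("halving the step leaves the settled state unchanged to 1e-3", {
  p <- quiet_bg(); w <- bg_weights()
  for (D in c(0.22, 0.55)) {
    run <- function(dt) {
      levotap:::.bg_core(D = D, params = unclass(p), weights = unclass(w),
                         dt = dt, settle_ms = 0, t_max_ms = 3000,
                         threshold = 0.9999999, physio_delay_ms = 0,
                         mode = 0L, S_init = c(1, 0), record_traces = FALSE,
                         thin = 1L, clamp_H = FALSE,
                         init_state = NULL)$final_state
    }
    expect_lt(max(abs(run(1) - run(0.5))), 1e-3)
  }
})

test_that("cholinergic ablation flattens the dopamine dependence", {
  t_of <- function(D, clamp) {
    simulate_selection(c(1, 0), D, threshold = 0.9,
                       clamp_H = clamp)$selection_time
  }
  spread_intact <- abs(t_of(0.22, FALSE) - t_of(0.55, FALSE))
  spread_ablate <- abs(t_of(0.22, TRUE) - t_of(0.55, TRUE))
  expect_lt(spread_ablate, spread_intact)
})

test_that("noise-free runs are bit-identical; seeded noise is reproducible", {
  a <- run_tapping(0.3, default_prot(trial = 4000))
  b <- run_tapping(0.3, default_prot(trial = 4000))
  expect_identical(a$tap_times, b$tap_times)
  expect_identical(a$frequency_hz, b$frequency_hz)
  noisy <- bg_params(sigma_noise = 0.1)
  set.seed(7)
  n1 <- run_tapping(0.3, default_prot(trial = 4000), params = noisy)
  set.seed(7)
  n2 <- run_tapping(0.3, default_prot(trial = 4000), params = noisy)
  expect_identical(n1$tap_times, n2$tap_times)
  expect_false(identical(a$tap_times, n1$tap_times))
})

test_that("weight validation enforces the printed sign pattern", {
  expect_error(bg_weights(W_IG = 12), "W_IG")
  expect_error(bg_weights(L = 0.5), "L")
  expect_error(bg_weights(w_NH = -1), "w_NH")
  expect_error(bg_params(beta = 1), "beta")
  expect_silent(levotap:::validate_bg_weights(unclass(bg_weights())))
})
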