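test_that("infusion rate is dose/duration inside the window and conserves dose", {
  s <- infusion_schedule(dose_ug = 1e5, duration_min = 30)
  expect_equal(infusion_rate(s, 10), 1e5 / 30)
  expect_equal(infusion_rate(s, 45), 0)
  expect_equal(infusion_rate(s, c(0, 29.999, 30)), c(1e5 / 30, 1e5 / 30, 0))
  # integral over any horizon covering the window equals the dose exactly
  igr <- stats::integrate(function(t) infusion_rate(s, t), 0, 240,
                          subdivisions = 2000L, rel.tol = 1e-10)
  expect_equal(igr$value, 1e5, tolerance = 1e-8)
})

test_that("plasma simulation: zero input and mass balance limits", {
  s <- infusion_schedule(1e5, 30)
  p <- pk_params(k12 = 2, k21 = 1.5, ketot = 0.5)
  # zero dose ~ zero state: simulate with dose after the horizon
  s_late <- infusion_schedule(1e5, 30, t_start_min = 500)
  sim0 <- simulate_plasma(p, s_late, seq(0, 240, by = 30))
  expect_true(all(sim0$c1 == 0) && all(sim0$c2 == 0))
  # no elimination: V1 c1 + V2 c2 approaches the administered amount
  p0 <- pk_params(k12 = 2, k21 = 1.5, ketot = 0)
  sim <- simulate_plasma(p0, s, c(60, 120, 240))
  mass <- p0$V1 * sim$c1 + p0$V2 * sim$c2   # mg
  expect_equal(mass, rep(100, 3), tolerance = 1e-6)
})

test_that("plasma simulation is linear in dose and non-negative", {
  p <- pk_params(k12 = 1.77, k21 = 1.26, ketot = 0.58)
  tt <- seq(0, 240, by = 10)
  s1 <- infusion_schedule(1e5, 30)
  s2 <- infusion_schedule(2e5, 30)
  a <- simulate_plasma(p, s1, tt)
  b <- simulate_plasma(p, s2, tt)
  expect_true(all(a$c1 >= 0) && all(a$c2 >= 0))
  expect_equal(b$c1, 2 * a$c1, tolerance = 1e-7)
})

test_that("ODE route agrees with the matrix-exponential oracle", {
  tab <- ld_patients()
  s <- infusion_schedule(1e5, 30)
  tt <- seq(5, 240, by = 5)
  for (i in c(1, 5)) { # fastest and slowest distribution kinetics
    p <- pk_params(k12 = tab$k12[i], k21 = tab$k21[i], ketot = tab$ketot[i])
    sim <- simulate_plasma(p, s, tt)
    orc <- matexp_plasma(p, s, tt)
    expect_lt(max(abs(sim$c1 - orc[, 1]) / pmax(orc[, 1], 1e-9)), 1e-6)
    expect_lt(max(abs(sim$c2 - orc[, 2]) / pmax(orc[, 2], 1e-9)), 1e-6)
  }
})

test_that("c1 peaks near the end of the absorption window then decays", {
  # group 1 subject 1 constants, standard volumes, 100 mg over 30 min
  p <- pk_params(k12 = 10.0, k21 = 9.11, ketot = 0.80)
  s <- infusion_schedule(1e5, 30)
  tt <- seq(0, 240, by = 1)
  sim <- simulate_plasma(p, s, tt)
  t_peak <- sim$time[which.max(sim$c1)]
  expect_lte(abs(t_peak - 30), 2)
  after <- sim$c1[sim$time >= 31]
  expect_true(all(diff(after) < 1e-12))
})

test_that("noise-free parameter recovery is within 1%", {
  s <- infusion_schedule(1e5, 30)
  tt <- c(seq(15, 90, by = 15), seq(120, 180, by = 30))
  p_true <- pk_params(k12 = 1.77, k21 = 1.26, ketot = 0.58)
  obs <- simulate_plasma(p_true, s, tt) |> dplyr::select(time, value = c1)
  fit <- fit_pk(obs, s, init = pk_params(k12 = 1, k21 = 1, ketot = 1))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$k12 / 1.77 - 1), 0.01)
  expect_lt(abs(fit$params$k21 / 1.26 - 1), 0.01)
  expect_lt(abs(fit$params$ketot / 0.58 - 1), 0.01)
  expect_lt(fit$cost, 1e-8)
  # cost equals the criterion at the returned parameters
  resim <- simulate_plasma(fit$params, s, tt)
  expect_equal(fit$cost, sum((resim$c1 - obs$value)^2), tolerance = 1e-4)
})

test_that("fitting does not worsen the criterion and flags short series", {
  s <- infusion_schedule(1e5, 30)
  tt <- seq(15, 120, by = 15)
  init <- pk_params(k12 = 2, k21 = 2, ketot = 0.5)
  obs <- simulate_plasma(init, s, tt) |> dplyr::select(time, value = c1)
  fit <- fit_pk(obs, s, init = init)
  cost_init <- sum((simulate_plasma(init, s, tt)$c1 - obs$value)^2)
  expect_lte(fit$cost, cost_init + 1e-12)
  expect_error(fit_pk(obs[1:3, ], s, init), "under-determined")
})

test_that("stochastic recovery: 2% multiplicative noise stays within 10%", {
  # group 2 subject 2 constants at the stated noise level, fixed seed
  s <- infusion_schedule(1e5, 30)
  tt <- c(seq(15, 90, by = 15), seq(120, 180, by = 30))
  p_true <- pk_params(k12 = 1.77, k21 = 1.26, ketot = 0.58)
  clean <- simulate_plasma(p_true, s, tt)$c1
  set.seed(42)
  obs <- tibble::tibble(time = tt, value = clean * exp(rnorm(length(tt), 0, 0.02)))
  fit <- fit_pk(obs, s, init = pk_params(k12 = 1, k21 = 1, ketot = 1))
  rel <- abs(c(fit$params$k12, fit$params$k21, fit$params$ketot) /
               c(1.77, 1.26, 0.58) - 1)
  expect_lt(max(rel), 0.10)
})

test_that("tidy and glance summarise a fit", {
  s <- infusion_schedule(1e5, 30)
  tt <- seq(15, 120, by = 15)
  p <- pk_params(k12 = 2, k21 = 2, ketot = 0.5)
  obs <- simulate_plasma(p, s, tt) |> dplyr::select(time, value = c1)
  fit <- fit_pk(obs, s, init = p, restarts = 0)
  td <- tidy(fit)
  expect_equal(td$term, c("k12", "k21", "ketot"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, length(tt))
  expect_true(is.logical(gl$converged))
})

test_that("invalid parameters are rejected", {
  expect_error(pk_params(k12 = -1, k21 = 1, ketot = 1), "positive")
  expect_error(pk_params(k12 = 1, k21 = 1, ketot = 1, V1 = 0), "positive")
  expect_error(simulate_plasma(pk_params(1, 1, 1),
                               infusion_schedule(1e5, 30),
                               c(10, 5)), "increasing")
})
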