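test_that("mean waiting times reproduce closed-form moments", {
  p <- atc_params(lam = 1, nb = 1)
  # unbinding: exponential mean 1/theta = 2
  st <- regime_state("Y", 3, 0L, 1L)
  mwt <- mean_waiting_times(st, p)
  expect_equal(mwt$mean_time[mwt$channel == "unbind"], 2)
  # constant-hazard binding: flow pinned at x0 = b/delta gives 1/(kappa x0)
  pc <- titration_params(Omega = 1000, nb_Y = 1, beta_f_X = 2, beta_b_X = 2,
                         delta_X = 1, delta_Y = 1, kappa_Y0 = 2,
                         theta_Y0 = 0.5)
  mc <- mean_waiting_times(regime_state("X", 2, 0L, 0L), pc)
  expect_equal(mc$mean_time[mc$channel == "bind"], 1 / (2 * 2),
               tolerance = 1e-8)
  # ramp-up binding mean: quadrature cross-checked by Monte Carlo
  m0 <- mean_waiting_times(regime_state("X", 0, 0L, 0L), p)
  quad <- m0$mean_time[m0$channel == "bind"]
  set.seed(2)
  f <- linear_flow(2, 1, 0)
  mc_mean <- mean(vapply(runif(2e4), function(u) {
    sample_binding_time(f, 1, u)
  }, numeric(1)))
  expect_lt(abs(quad - mc_mean), 3 * sqrt(0.48 / 2e4) + 1e-3)
})

test_that("a constant-rate two-state promoter has ADL period 1/k+ + 1/k-", {
  # constant flow (b = delta * x0) with both production rates of gene Y
  # zero: binding at kappa*x0, unbinding at theta, nothing else
  p <- titration_params(Omega = 1000, nb_Y = 1, beta_f_X = 2, beta_b_X = 2,
                        beta_f_Y = 0, beta_b_Y = 0, delta_X = 1,
                        delta_Y = 1, kappa_Y0 = 2, theta_Y0 = 0.5)
  res <- simulate_adl(p, init = regime_state("X", 2, 0L, 0L))
  k_plus <- 2 * 2  # kappa * x0
  k_minus <- 0.5
  expect_equal(attr(res, "period"), 1 / k_plus + 1 / k_minus,
               tolerance = 1e-8)
})

test_that("the ATC ADL cycles through all four states with zero period variance", {
  res <- simulate_adl(atc_params(lam = 1, nb = 1), n_cycles = 4)
  cyc <- attr(res, "cycle_states")
  states <- unique(paste(cyc$regime, cyc$s_Y))
  expect_setequal(states, c("X 0", "X 1", "Y 0", "Y 1"))

  # independent oracle for the period: quadrature mean binding time,
  # exact titration times, exponential mean unbinding
  Tb <- integrate(function(t) survival_binding(t, linear_flow(2, 1, 0), 1),
                  0, Inf, rel.tol = 1e-10)$value
  w1 <- 2 * (1 - exp(-Tb))
  t_tit_x <- log(1 + w1 / 8)
  Tu <- 1 / 0.5
  y2 <- 8 * (1 - exp(-Tu))
  t_tit_y <- log(1 + y2 / 2)
  expect_equal(attr(res, "period"), Tb + t_tit_x + Tu + t_tit_y,
               tolerance = 1e-7)

  # detected periods on the ADL trajectory are exactly constant
  ps <- detect_periods(res)
  expect_gte(length(ps$periods), 2)
  expect_lt(var(ps$periods), 1e-8)
  expect_equal(mean(ps$periods), attr(res, "period"), tolerance = 1e-6)
})

test_that("the RTC ADL also runs a four-state deterministic cycle", {
  res <- simulate_adl(rtc_params(lam = 1, nb = 1), n_cycles = 3)
  cyc <- attr(res, "cycle_states")
  expect_setequal(unique(paste(cyc$regime, cyc$s_X)),
                  c("X 0", "X 1", "Y 0", "Y 1"))
  expect_gt(attr(res, "period"), 0)
})

test_that("ADL period lies inside the stochastic period distribution's support", {
  p <- atc_params(lam = 1, nb = 1)
  adl_period <- attr(simulate_adl(p), "period")
  ps <- tidy(detect_periods(simulate_linear_pdmp(p, t_end = 1500, seed = 4)))
  expect_gt(adl_period, min(ps$period))
  expect_lt(adl_period, max(ps$period))
})

test_that("an absorbing configuration is reported as non-oscillatory", {
  # inhibitor produced faster than the activator with an empty promoter:
  # the y-positive regime persists and no channel can ever fire
  p <- titration_params(Omega = 1000, nb_Y = 1, beta_f_X = 2, beta_b_X = 2,
                        beta_f_Y = 5, beta_b_Y = 10, delta_X = 1,
                        delta_Y = 1, kappa_Y0 = 1, theta_Y0 = 0.5)
  expect_error(simulate_adl(p, init = regime_state("Y", 0, 0L, 0L)),
               class = "pdmposc_simulation_error")
})
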