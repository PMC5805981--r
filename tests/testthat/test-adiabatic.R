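test_that("the promoter QSD is the detailed-balance geometric chain", {
  p1 <- titration_params(nb_Y = 1, kappa_Y0 = 1, theta_Y0 = 1)
  expect_equal(promoter_qsd(1, p1, "Y")$prob, c(0.5, 0.5))
  p3 <- atc_params(lam = 1, nb = 3)
  expect_equal(promoter_qsd(0, p3, "Y")$prob, c(1, 0, 0, 0))
  # ratio kappa*x/theta = 2 at x = 1: geometric weights (1,2,4,8)/15
  qs <- promoter_qsd(1, p3, "Y")$prob
  expect_equal(qs, c(1, 2, 4, 8) / 15)

  # brute-force oracle: stationary vector of the explicit 4x4 generator
  birth <- p3$kappa_Y * 1
  death <- p3$theta_Y
  Q <- matrix(0, 4, 4)
  for (s in 1:3) Q[s, s + 1] <- birth
  for (s in 2:4) Q[s, s - 1] <- death
  diag(Q) <- -rowSums(Q)
  ns <- eigen(t(Q))
  v <- Re(ns$vectors[, which.min(abs(ns$values))])
  expect_equal(qs, v / sum(v), tolerance = 1e-10)

  # degenerate theta = 0: absorbed at full occupancy
  p0 <- titration_params(nb_Y = 2, kappa_Y0 = 1, theta_Y0 = 0)
  expect_equal(promoter_qsd(1, p0, "Y")$prob, c(0, 0, 1))
})

test_that("effective production interpolates free and bound rates", {
  p <- atc_params(lam = 1, nb = 1)
  expect_equal(effective_production(0, p, "Y"), 0)
  # pi_0 = 0.5 at kappa x = theta (x = 0.5): midpoint of 0 and 10
  expect_equal(effective_production(0.5, p, "Y"), 5)
  expect_equal(effective_production(1.3, p, "X"), 2) # constitutive gene
})

test_that("the analytic beta_eff derivative matches a numeric difference", {
  p <- rtc_params(lam = 1, nb = 3)
  h <- 1e-6
  for (x in c(0.1, 0.5, 1, 2, 10)) {
    num <- (effective_production(x + h, p, "X") -
              effective_production(x - h, p, "X")) / (2 * h)
    ana <- pdmposc:::effective_production_slope(x, p, "X")
    expect_lt(abs(num - ana), 1e-5)
    expect_lt(ana, 0) # repressor: effective rate decreases in x
  }
})

test_that("the Jacobian trace has the stated structure", {
  atc <- atc_params(lam = 1, nb = 1)
  expect_equal(jacobian_trace(0, 0, atc), -2)
  # trace decreases linearly along x + y at fixed derivative term
  expect_equal(jacobian_trace(1, 2, atc), -2 - 10 * 3)
  rtc <- rtc_params(lam = 1, nb = 1)
  expect_lt(jacobian_trace(0.5, 0, rtc), -(rtc$delta_X + rtc$delta_Y))
})

test_that("Bendixson certificate holds for both circuits, fails for self-activation", {
  for (p in list(atc_params(lam = 1, nb = 1), rtc_params(lam = 1, nb = 3))) {
    chk <- no_limit_cycle_check(p, n_grid = 60)
    expect_true(chk$no_limit_cycle)
    expect_lt(chk$worst_trace, 0)
  }
  # single-point grid at the origin: trace is -(delta_X + delta_Y)
  chk0 <- no_limit_cycle_check(atc_params(lam = 1, nb = 1), n_grid = 1)
  expect_true(chk0$no_limit_cycle)
  expect_equal(chk0$worst_trace, -2)

  # constructed violation: strong positive autoregulation of X, no titration
  sa <- titration_params(nb_X = 1, beta_f_X = 0, beta_b_X = 50,
                         beta_f_Y = 1, beta_b_Y = 1, delta_X = 1,
                         delta_Y = 1, kappa_X0 = 1, theta_X0 = 1, alpha = 0)
  chk_sa <- no_limit_cycle_check(sa, n_grid = 60)
  expect_false(chk_sa$no_limit_cycle)
})

test_that("adiabatic ODE trajectories settle to a fixed point", {
  rep <- check_adiabatic(atc_params(lam = 1, nb = 1), n_init = 5,
                         t_end = 150, seed = 2, n_grid = 20)
  expect_true(rep$all_converged)
  # residual of the RHS at the reached equilibrium is tiny
  fp <- rep$fixed_points[1, ]
  rhs <- adiabatic_rhs(fp$x_end, fp$y_end, atc_params(lam = 1, nb = 1))
  expect_lt(max(abs(rhs)), 1e-5)

  # alpha = 0 decouples x: it relaxes to its effective-production fixed point
  p0 <- titration_params(beta_f_X = 4, beta_b_X = 4, delta_X = 2,
                         delta_Y = 1, alpha = 0)
  tr <- simulate_adiabatic(p0, init = c(0, 0), t_end = 20)
  expect_equal(tr$x[nrow(tr)], 2, tolerance = 1e-6)
})
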