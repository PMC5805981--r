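test_that("closed-form flow, hitting time and survival match reference values", {
  f <- linear_flow(b = 2, delta = 1, x0 = 0)
  expect_equal(closed_flow(f, 0), 0)
  expect_equal(closed_flow(f, 1), 2 * (1 - exp(-1)))
  expect_equal(closed_flow(f, 50), 2, tolerance = 1e-8)

  expect_equal(hitting_time_zero(linear_flow(-8, 1, 2)), log(1.25))
  expect_equal(hitting_time_zero(linear_flow(0, 1, 0)), 0)
  expect_equal(hitting_time_zero(linear_flow(2, 1, 1)), Inf)

  expect_equal(survival_binding(0, f, 1), 1)
  expect_equal(survival_binding(3, f, 0), 1)
  expect_equal(survival_binding(1, f, 1),
               exp(-(2 - 2 * (1 - exp(-1)))), tolerance = 1e-12)
  expect_error(survival_binding(1, f, -1), class = "pdmposc_parameter_error")
})

test_that("closed forms agree with numeric ODE/quadrature oracles on random draws", {
  set.seed(7)
  for (i in 1:100) {
    b <- runif(1, -5, 5)
    d <- runif(1, 0.2, 3)
    x0 <- runif(1, 0, 5)
    kappa <- runif(1, 0.1, 3)
    f <- linear_flow(b, d, x0)
    t_test <- runif(1, 0.1, 3)

    # flow vs numeric ODE integration
    ode <- deSolve::ode(y = x0, times = c(0, t_test),
                        func = function(t, y, p) list(b - d * y),
                        rtol = 1e-11, atol = 1e-12)
    expect_lt(abs(closed_flow(f, t_test) - ode[2, 2]), 1e-8)

    # survival vs adaptive quadrature of the hazard, on the x >= 0 domain
    t_surv <- min(t_test, 0.95 * hitting_time_zero(f))
    quad <- integrate(function(s) closed_flow(f, s), 0, t_surv,
                      rel.tol = 1e-11)$value
    expect_lt(abs(survival_binding(t_surv, f, kappa) - exp(-kappa * quad)),
              1e-8)

    # hitting time vs bisection on the closed flow
    if (b < 0 && x0 > 0) {
      ts <- hitting_time_zero(f)
      br <- uniroot(function(s) closed_flow(f, s), c(0, 100), tol = 1e-12)
      expect_lt(abs(ts - br$root), 1e-8)
    }
  }
})

test_that("binding-time sampling inverts the survival function", {
  f <- linear_flow(2, 1, 0)
  # u -> 1 gives t -> 0
  expect_lt(sample_binding_time(f, 1, 1 - 1e-9), 1e-3)
  # degenerate constant flow: exponential with rate kappa*x0, median ln2/(k x0)
  fc <- linear_flow(b = 1 * 2, delta = 1, x0 = 2)
  expect_equal(sample_binding_time(fc, 1.5, 0.5), log(2) / (1.5 * 2),
               tolerance = 1e-7)
  # inverse-transform property: empirical CDF matches 1 - S
  set.seed(11)
  u <- runif(1e4)
  samples <- vapply(u, function(ui) sample_binding_time(f, 1, ui),
                    numeric(1))
  ks <- suppressWarnings(
    ks.test(samples, function(q) 1 - survival_binding(q, f, 1)))
  expect_gt(ks$p.value, 0.01)
  # bounded hazard: b <= 0 can leave the binding unrealized
  expect_identical(sample_binding_time(linear_flow(-1, 1, 0.5), 0.2, 0.5),
                   Inf)
  expect_error(sample_binding_time(f, 1, 0), class = "pdmposc_parameter_error")
})

test_that("binding from an empty start is relatively more coherent", {
  # the waiting-time CV (sd/mean) is smallest when x0 = 0: the flow must
  # ramp up before binding becomes likely, concentrating the distribution
  cv_of <- function(x0) {
    f <- linear_flow(2, 1, x0)
    m <- integrate(function(t) survival_binding(t, f, 1), 0, Inf,
                   rel.tol = 1e-10)$value
    m2 <- 2 * integrate(function(t) t * survival_binding(t, f, 1), 0, Inf,
                        rel.tol = 1e-10)$value
    sqrt(m2 - m^2) / m
  }
  expect_lt(cv_of(0), cv_of(2))
  expect_lt(cv_of(2), cv_of(5) + 1e-9) # exponential vs front-loaded hazard
})

test_that("net production combines the two genes' rates by regime", {
  p <- atc_params(lam = 1, nb = 1)
  expect_equal(net_production(0, 0, p, "X"), 2)
  expect_equal(net_production(0, 1, p, "X"), -8)
  expect_equal(net_production(0, 1, p, "Y"), 8)
  sym <- titration_params(nb_Y = 1, beta_f_X = 3, beta_b_X = 3,
                          beta_f_Y = 3, beta_b_Y = 3)
  expect_equal(net_production(0, 0, sym, "X"), 0)
  expect_equal(net_production(0, 0, sym, "Y"), 0)
})

test_that("linearized ATC predominantly runs the anticlockwise full cycle", {
  p <- atc_params(lam = 1, nb = 1)
  traj <- simulate_linear_pdmp(p, t_end = 2000, seed = 17)
  ev <- attr(traj, "events")
  expect_gt(nrow(ev), 500)
  # regime switches happen exactly when the positive species dies out
  sw <- traj[!is.na(traj$event) & traj$event == "titration_switch", ]
  expect_lt(max(sw$x + sw$y), 1e-9)
  # after binding, titration (full cycle) beats dissociation most of the time
  ev_next <- ev$event[-1L]
  after_bind <- ev_next[ev$event[-nrow(ev)] == "bind_Y"]
  expect_gt(mean(after_bind == "titration_switch"), 0.5)
  # all four linearized states are realized
  x_pos <- traj$x > 1e-12
  states <- unique(paste(ifelse(x_pos, "X", "Y"), traj$s_Y))
  expect_setequal(states, c("X 0", "X 1", "Y 0", "Y 1"))
})

test_that("with no dissociation the bound state always exits by titration", {
  p <- titration_params(Omega = 1000, nb_Y = 1, beta_f_X = 2, beta_b_X = 2,
                        beta_f_Y = 0, beta_b_Y = 10, delta_X = 1,
                        delta_Y = 1, kappa_Y0 = 1, theta_Y0 = 0, alpha = 10)
  traj <- simulate_linear_pdmp(p, init = regime_state("X", 2, 0L, 1L),
                               t_end = 20, seed = 3)
  ev <- attr(traj, "events")
  expect_equal(ev$event[1L], "titration_switch")
  expect_false(any(ev$event == "unbind_Y"))
})

test_that("the linear model underestimates short promoter cycles vs the CME", {
  p <- atc_params(lam = 1, nb = 1)
  proto <- period_protocol(method = "promoter")
  pc <- tidy(detect_periods(simulate_cme(p, t_end = 6000, seed = 5), proto))
  pl <- tidy(detect_periods(simulate_linear_pdmp(p, t_end = 6000, seed = 6),
                            proto))
  expect_gt(nrow(pc), 1000)
  expect_gt(nrow(pl), 1000)
  expect_lt(mean(pl$period < 2), mean(pc$period < 2))
})
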