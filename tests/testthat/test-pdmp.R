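test_that("with no hazards the PDMP reduces to the deterministic ODE", {
  # unregulated, no titration: x(t) = b/d + (x0 - b/d) e^{-dt}
  p <- titration_params(beta_f_X = 2, beta_b_X = 2, delta_X = 1,
                        delta_Y = 1, alpha = 0)
  traj <- simulate_pdmp(p, init = hybrid_state(0, 0), t_end = 5, seed = 1)
  expect_equal(attr(traj, "n_events"), 0L)
  expect_equal(traj$x, 2 * (1 - exp(-traj$time)), tolerance = 1e-7)
  expect_equal(traj$y, rep(0, nrow(traj)))
})

test_that("frozen-drift constant hazards give exponential inter-switch times", {
  # beta = delta = alpha = 0 freezes x, so binding (kappa*x) and unbinding
  # (theta) are constant-rate and their waiting times exponential
  p <- telegraph_params(kappa0 = 2, theta0 = 2, nb = 1L)
  x0 <- 2
  traj <- simulate_pdmp(p, init = hybrid_state(x0, 0), t_end = 400,
                        seed = 21, snapshot_dt = 0.5)
  ev <- attr(traj, "events")
  expect_gt(nrow(ev), 600)
  waits <- diff(c(0, ev$time))
  is_bind <- ev$event == "bind_Y"
  ks_bind <- suppressWarnings(ks.test(waits[is_bind], "pexp",
                                      rate = 2 * x0))
  ks_unb <- suppressWarnings(ks.test(waits[!is_bind], "pexp", rate = 2))
  expect_gt(ks_bind$p.value, 0.01)
  expect_gt(ks_unb$p.value, 0.01)
  expect_true(all(abs(traj$x - x0) < 1e-8))
})

test_that("first binding time follows the analytic survival law", {
  # ATC from (0,0,0,0): before the first binding y stays 0 and
  # x(t) = 2(1 - e^{-t}); hazard kappa * x with kappa = 1
  p <- atc_params(lam = 1, nb = 1)
  times <- vapply(1:400, function(i) {
    tr <- simulate_pdmp(p, t_end = 12, seed = 5000 + i, snapshot_dt = 1)
    ev <- attr(tr, "events")
    if (nrow(ev) == 0) NA_real_ else ev$time[1L]
  }, numeric(1))
  times <- times[!is.na(times)]
  expect_gt(length(times), 390) # S(12) ~ 5e-10: censoring negligible
  cdf <- function(q) 1 - exp(-(2 * q - 2 * (1 - exp(-q))))
  ks <- suppressWarnings(ks.test(times, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("PDMP runs are seed-reproducible and respect state invariants", {
  p <- atc_params(lam = 1, nb = 3)
  t1 <- simulate_pdmp(p, t_end = 40, seed = 8)
  t2 <- simulate_pdmp(p, t_end = 40, seed = 8)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(t1$x >= 0 & t1$y >= 0))
  expect_true(all(t1$s_Y %in% 0:3))
  # each switching event changes s by exactly +-1
  ev_rows <- which(!is.na(t1$event))
  s_path <- t1$s_Y[c(1L, ev_rows + 1L)]
  s_path <- s_path[!is.na(s_path)]
  expect_true(all(abs(diff(s_path)) <= 1))
})

test_that("occupancy statistics are time-weighted and normalized", {
  # constant-state trajectory
  p <- titration_params(nb_Y = 1)
  tr <- simulate_cme(p, init = discrete_state(0, 0, 0, 1), t_end = 3,
                     seed = 1, snapshot_dt = 0.5)
  occ <- occupancy_stats(tr, gene = "Y")
  expect_equal(occ$fraction[occ$s == 1], 1)

  # symmetric two-state telegraph: equal occupancies
  pt <- telegraph_params(kappa0 = 1, theta0 = 2, nb = 1L)
  tr2 <- simulate_pdmp(pt, init = hybrid_state(2, 0), t_end = 600,
                       seed = 31, snapshot_dt = 0.2)
  occ2 <- occupancy_stats(tr2, gene = "Y")
  expect_equal(sum(occ2$fraction), 1)
  expect_lt(abs(occ2$fraction[occ2$s == 1] - 0.5), 0.05)
})

test_that("multi-site dynamics stay trapped in the s = 0/1 mini-cycle", {
  p <- atc_params(lam = 1, nb = 3)
  traj <- simulate_pdmp(p, t_end = 300, seed = 13)
  occ <- occupancy_stats(traj, gene = "Y")
  lower <- sum(occ$fraction[occ$s <= 1])
  upper <- sum(occ$fraction[occ$s >= 2])
  expect_lt(upper, 0.2 * lower)
})
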