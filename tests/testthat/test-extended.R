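test_that("extended parameter sets are validated for structural completeness", {
  expect_error(kb_params(list(tx_A = 1)), "incomplete",
               class = "pdmposc_parameter_error")
  good <- kb_test_params()
  expect_s3_class(good, "kb_params")
  bad <- unclass(good)
  bad$kappa_b <- NA
  expect_error(kb_params(bad), class = "pdmposc_parameter_error")

  # shipped templates are placeholders: loading them must fail loudly
  tmpl <- system.file("extdata", "kb_params.yaml", package = "pdmposc")
  expect_error(read_extended_params(tmpl),
               class = "pdmposc_parameter_error")
  tmpl2 <- system.file("extdata", "vkbl_params.yaml", package = "pdmposc")
  expect_error(read_extended_params(tmpl2),
               class = "pdmposc_parameter_error")
})

test_that("KB drift and hazards honour distributive multiplicities", {
  p <- kb_test_params()
  st <- list(r_A = 1, r_I = 1, A = 1, A2 = 2, I = 1, AI = 0, G = 0L)
  h0 <- kb_hazards(st, p)
  expect_equal(unname(h0["bind"]), p$kappa_b * p$G_max * 2)
  expect_equal(unname(h0["unbind"]), 0)
  st$G <- p$G_max
  hmax <- kb_hazards(st, p)
  expect_equal(unname(hmax["bind"]), 0)
  expect_equal(unname(hmax["unbind"]), p$theta_b * p$G_max)

  # all rates zero: frozen system
  zero <- kb_params(setNames(as.list(rep(0, 19)),
                             pdmposc:::kb_required_keys))
  stz <- list(r_A = 1, r_I = 1, A = 1, A2 = 1, I = 1, AI = 1, G = 0L)
  expect_true(all(kb_drift(stz, zero) == 0))
  expect_true(all(kb_hazards(stz, zero) == 0))
})

test_that("dimerization relaxes to its mass-action equilibrium", {
  # only 2A <-> A2 active: equilibrium ratio A2/A^2 = k_f/k_r
  p <- kb_test_params(tx_A = 0, tx_I_free = 0, tx_I_bound = 0, tl_A = 0,
                      tl_I = 0, d_rA = 0, d_rI = 0, d_A = 0, d_A2 = 0,
                      d_I = 0, d_AI = 0, k_dim_f = 2, k_dim_r = 3,
                      k_het_f = 0, k_het_r = 0, kappa_b = 0, theta_b = 0)
  init <- list(r_A = 0, r_I = 0, A = 5, A2 = 0, I = 0, AI = 0, G = 0L)
  tr <- simulate_kb_pdmp(p, init = init, t_end = 60, seed = 1)
  A_end <- tr$A[nrow(tr)]
  A2_end <- tr$A2[nrow(tr)]
  expect_equal(A2_end / A_end^2, 2 / 3, tolerance = 1e-5)
  # mass conservation of monomer equivalents
  expect_equal(A_end + 2 * A2_end, 5, tolerance = 1e-6)
})

test_that("mRNA-lifetime rescaling leaves the protein synthesis flux fixed", {
  p <- kb_test_params()
  expect_equal(unclass(rescale_mrna(p, 1)), unclass(p))
  mrna_ss <- function(q) q$tx_A / q$d_rA
  flux <- function(q) q$tl_A * mrna_ss(q)
  base <- flux(p)
  for (w in c(4, 16)) {
    q <- rescale_mrna(p, w)
    expect_equal(flux(q), base)
    expect_equal(q$d_rA, p$d_rA * w) # faster mRNA turnover
  }
})

test_that("reduced KB dynamics fire deterministic bindings at the mean time", {
  # constant A2 (no production or decay): binding time is exactly
  # 1/(kappa_b (G_max - G) [A2]); theta_b = 0 so only bindings occur
  p <- kb_test_params(tx_A = 0, tx_I_free = 0, tx_I_bound = 0, tl_A = 0,
                      tl_I = 0, d_rA = 0, d_rI = 0, d_A = 0, d_A2 = 0,
                      d_I = 0, d_AI = 0, k_dim_f = 0, k_dim_r = 0,
                      k_het_f = 0, k_het_r = 0, kappa_b = 0.5, theta_b = 0,
                      G_max = 2)
  init <- list(r_A = 0, r_I = 0, A = 0, A2 = 3, I = 0, AI = 0, G = 0L)
  tr <- simulate_kb_reduced(p, init = init, t_end = 10, seed = 1)
  ev <- attr(tr, "events")
  expect_equal(ev$event, c("bind", "bind"))
  t1 <- 1 / (0.5 * 2 * 3)
  t2 <- t1 + 1 / (0.5 * 1 * 3)
  expect_equal(ev$time, c(t1, t2), tolerance = 1e-5)
  expect_equal(max(tr$G), 2L) # saturates at G_max, then nothing
})

test_that("the mRNA-rescale sweep reports period statistics per grid point", {
  p <- kb_test_params()
  sw <- sweep_mrna_rescale(p, w = c(1, 4), t_end = 300, seed = 11)
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$w, c(1, 4))
  expect_gte(sw$n_cycles[1], 2)
  expect_true(all(is.finite(sw$mean_period)))
})

test_that("VKBL hazards and promoter occupancy follow the telegraph law", {
  p <- vkbl_test_params()
  st <- list(m_A = 0, m_R = 0, A = 2, R = 0, C = 0, G_A = 1L, G_R = 0L)
  h <- vkbl_hazards(st, p)
  expect_equal(unname(h["bind_A"]), 0) # already bound
  expect_equal(unname(h["unbind_A"]), p$theta_A)
  expect_equal(unname(h["bind_R"]), p$kappa_R * 2)

  # frozen A: gene-A occupancy is kappa_A*A / (kappa_A*A + theta_A)
  pf <- vkbl_test_params(tx_A_free = 0, tx_A_bound = 0, tx_R_free = 0,
                         tx_R_bound = 0, tl_A = 0, tl_R = 0, d_mA = 0,
                         d_mR = 0, d_A = 0, d_R = 0, k_C = 0,
                         kappa_A = 1, theta_A = 2, kappa_R = 0,
                         theta_R = 1)
  init <- list(m_A = 0, m_R = 0, A = 2, R = 0, C = 0, G_A = 0L, G_R = 0L)
  tr <- simulate_vkbl_pdmp(pf, init = init, t_end = 400, seed = 9,
                           snapshot_dt = 0.2)
  expect_true(all(tr$A == 2))
  expect_true(all(tr$G_R == 0L))
  occ <- sum(diff(tr$time) * (tr$G_A[-nrow(tr)] == 1L)) /
    (tr$time[nrow(tr)] - tr$time[1L])
  expected <- 2 / (2 + 2)
  expect_lt(abs(occ - expected), 0.05)
})
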