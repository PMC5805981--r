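# Shared fixtures for the test suite (all generated in code).

# a "telegraph" parameter set: no production/degradation/titration, so with
# pinned copy numbers the regulated promoter is a two-state (or birth-death)
# chain with constant rates kappa*N_X/Omega and theta
telegraph_params <- function(kappa0 = 1, theta0 = 0.5, nb = 1L, lam = 1) {
  titration_params(Omega = 1000, lam = lam, nb_X = 0L, nb_Y = nb,
                   beta_f_X = 0, beta_b_X = 0, beta_f_Y = 0, beta_b_Y = 0,
                   delta_X = 0, delta_Y = 0,
                   kappa_Y0 = kappa0, theta_Y0 = theta0, alpha = 0)
}

# synthetic KB rate set: structural testing only, not the published values
kb_test_params <- function(...) {
  base <- list(tx_A = 1, tx_I_free = 0.1, tx_I_bound = 2, tl_A = 2, tl_I = 2,
               d_rA = 1, d_rI = 1, d_A = 0.2, d_A2 = 0.2, d_I = 0.2,
               d_AI = 0.2, k_dim_f = 1, k_dim_r = 1, k_het_f = 5,
               k_het_r = 0.1, kappa_b = 0.5, theta_b = 0.2,
               G_max = 3, V = 1000)
  mods <- list(...)
  base[names(mods)] <- mods
  kb_params(base)
}

# synthetic VKBL rate set: structural testing only
vkbl_test_params <- function(...) {
  base <- list(tx_A_free = 5, tx_A_bound = 50, tx_R_free = 0.1,
               tx_R_bound = 5, tl_A = 5, tl_R = 1, d_mA = 1, d_mR = 0.5,
               d_A = 1, d_R = 0.2, k_C = 2, kappa_A = 1, theta_A = 50,
               kappa_R = 1, theta_R = 100, V = 1000)
  mods <- list(...)
  base[names(mods)] <- mods
  vkbl_params(base)
}

expect_within_3se <- function(estimate, truth, se) {
  expect_lt(abs(estimate - truth), 3 * se)
}
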