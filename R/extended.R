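# Structural PDMP engines for two published mechanistic variants of the
# activator-titration circuit: the KB model (explicit mRNA, activator
# homodimerization, distributive multi-site binding, reversible titration)
# and the VKBL model (activator self-activation, two one-site promoters).
# Numeric rate values are deliberately NOT built in: they belong to the
# original publications and are supplied by the user through a validated
# config (see the YAML templates under inst/extdata).

kb_required_keys <- c(
  "tx_A",                       # activator transcription (constitutive)
  "tx_I_free", "tx_I_bound",    # inhibitor transcription, G = 0 / G > 0
  "tl_A", "tl_I",               # translation rates
  "d_rA", "d_rI",               # mRNA degradation
  "d_A", "d_A2", "d_I", "d_AI", # protein/complex degradation
  "k_dim_f", "k_dim_r",         # 2A <-> A2
  "k_het_f", "k_het_r",         # A + I <-> AI (reversible titration)
  "kappa_b", "theta_b",         # dimer-promoter association/dissociation
  "G_max", "V"                  # binding sites, system size analogue
)

vkbl_required_keys <- c(
  "tx_A_free", "tx_A_bound",    # activator transcription, promoter free/bound
  "tx_R_free", "tx_R_bound",    # inhibitor transcription
  "tl_A", "tl_R",               # translation
  "d_mA", "d_mR",               # mRNA degradation
  "d_A", "d_R",                 # protein degradation
  "k_C",                        # A + R -> C association
  "kappa_A", "theta_A",         # A binding/unbinding at its own promoter
  "kappa_R", "theta_R",         # A binding/unbinding at the R promoter
  "V"
)

#' Extended-model parameter sets
#'
#' Validates a named rate map for the KB or VKBL model structure.  Every
#' required key must be present, numeric and non-negative; templates with
#' placeholder values ship under `inst/extdata` (`kb_params.yaml`,
#' `vkbl_params.yaml`) and can be loaded with [read_extended_params()].
#'
#' @param pars named list of rates.
#' @return The validated list, classed `kb_params` / `vkbl_params`.
#' @export
kb_params <- function(pars) {
  validate_extended(pars, kb_required_keys, "KB")
  structure(pars, class = "kb_params")
}

#' @rdname kb_params
#' @export
vkbl_params <- function(pars) {
  validate_extended(pars, vkbl_required_keys, "VKBL")
  structure(pars, class = "vkbl_params")
}

validate_extended <- function(pars, keys, model) {
  missing <- setdiff(keys, names(pars))
  if (length(missing)) {
    abort(paste0(model, " parameter set is structurally incomplete; missing: ",
                 paste(missing, collapse = ", ")),
          class = "pdmposc_parameter_error")
  }
  for (k in keys) {
    v <- pars[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort(paste0(model, " parameter `", k,
                   "` must be a single non-negative number (placeholders must be filled in)."),
            class = "pdmposc_parameter_error")
    }
  }
  invisible(TRUE)
}

#' @rdname kb_params
#' @param path YAML file with the rate map and a `model: KB` / `model: VKBL`
#'   key.
#' @export
read_extended_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  model <- toupper(cfg$model %||% "")
  pars <- cfg[setdiff(names(cfg), "model")]
  switch(model,
    KB = kb_params(pars),
    VKBL = vkbl_params(pars),
    abort("config must set `model:` to KB or VKBL.",
          class = "pdmposc_parameter_error")
  )
}

#' KB-model PDMP drift and switching hazards
#'
#' State: mRNA concentrations `r_A`, `r_I`; activator monomer `A` and
#' homodimer `A2`; inhibitor `I`; heterodimer `AI`; discrete promoter
#' occupancy `G` in `0..G_max`.  Drift: constitutive activator
#' transcription, promoter-dependent inhibitor transcription (`tx_I_bound`
#' once any site is bound), translation, degradations, dimerization
#' `2A <-> A2`, reversible titration `A + I <-> AI`.  Binding is
#' distributive, so hazards carry the combinatorial multiplicities:
#' binding `kappa_b (G_max - G) [A2]`, unbinding `theta_b G`.
#'
#' @param state named numeric vector or list with `r_A, r_I, A, A2, I, AI`
#'   and `G`.
#' @param p a [kb_params()] object.
#' @return `kb_drift()`: named derivative vector of the six concentrations;
#'   `kb_hazards()`: named vector `c(bind, unbind)`.
#' @export
kb_drift <- function(state, p) {
  G <- state$G
  if (G < 0 || G > p$G_max) {
    abort("G out of [0, G_max].", class = "pdmposc_state_error")
  }
  tx_I <- if (G > 0) p$tx_I_bound else p$tx_I_free
  dim_f <- p$k_dim_f * state$A^2
  dim_r <- p$k_dim_r * state$A2
  het_f <- p$k_het_f * state$A * state$I
  het_r <- p$k_het_r * state$AI
  c(r_A = p$tx_A - p$d_rA * state$r_A,
    r_I = tx_I - p$d_rI * state$r_I,
    A = p$tl_A * state$r_A - p$d_A * state$A - 2 * dim_f + 2 * dim_r -
      het_f + het_r,
    A2 = dim_f - dim_r - p$d_A2 * state$A2,
    I = p$tl_I * state$r_I - p$d_I * state$I - het_f + het_r,
    AI = het_f - het_r - p$d_AI * state$AI)
}

#' @rdname kb_drift
#' @export
kb_hazards <- function(state, p) {
  G <- state$G
  c(bind = p$kappa_b * (p$G_max - G) * max(state$A2, 0),
    unbind = p$theta_b * G)
}

#' Rescale mRNA lifetime at fixed protein output
#'
#' Multiplies both the mRNA degradation rates and the translation rates by
#' the factor `w`, so the steady-state translation flux
#' `translation * transcription / d_m` — and hence total protein level —
#' is invariant while the mRNA relaxation time `1/(w d_m)` shortens with
#' larger `w`.
#'
#' @param p a [kb_params()] object.
#' @param w positive rescale factor; `w = 1` is the identity.
#' @return A rescaled [kb_params()] object.
#' @export
rescale_mrna <- function(p, w) {
  stopifnot(inherits(p, "kb_params"), is.numeric(w), w > 0)
  p$d_rA <- p$d_rA * w
  p$d_rI <- p$d_rI * w
  p$tl_A <- p$tl_A * w
  p$tl_I <- p$tl_I * w
  p
}

kb_state_default <- function() {
  list(r_A = 0, r_I = 0, A = 0, A2 = 0, I = 0, AI = 0, G = 0L)
}

#' Simulate the KB-model PDMP
#'
#' Hybrid kinetic Monte Carlo with the same integrated-hazard event clock as
#' [simulate_pdmp()], over the KB drift/hazards.
#'
#' @param p a [kb_params()] object.
#' @param init state list as in [kb_drift()]; default all-zero.
#' @param t_end horizon.
#' @param seed RNG seed.
#' @param snapshot_dt stored sampling interval.
#' @return A `circuit_trajectory` tibble with the KB species columns and `G`.
#' @export
simulate_kb_pdmp <- function(p, init = kb_state_default(), t_end, seed,
                             snapshot_dt = 0.05) {
  stopifnot(inherits(p, "kb_params"))
  set.seed(seed)
  nms <- c("r_A", "r_I", "A", "A2", "I", "AI")
  drift <- function(cont, disc) {
    st <- as.list(c(setNames(cont, nms), G = disc[1L]))
    unname(kb_drift(st, p))
  }
  hazards <- function(cont, disc) {
    st <- as.list(c(setNames(cont, nms), G = disc[1L]))
    kb_hazards(st, p)
  }
  jump <- function(disc, ch) {
    disc[1L] <- disc[1L] + if (ch == "bind") 1L else -1L
    disc
  }
  res <- sim_pdmp_hybrid(drift, hazards, jump,
                         cont0 = unlist(init[nms]), disc0 = c(G = init$G),
                         t_end = t_end, snapshot_dt = snapshot_dt)
  df <- tibble::as_tibble(as.data.frame(res$cont))
  names(df) <- nms
  df <- dplyr::bind_cols(tibble::tibble(time = res$time), df,
                         tibble::tibble(G = as.integer(res$disc[, 1L]),
                                        event = res$event))
  events <- res$events
  events$G <- if (nrow(events)) as.integer(res$events_disc[, 1L]) else
    integer(0)
  new_trajectory(df, engine = "kb_pdmp", params = p, seed = seed,
                 events = events, n_events = res$n_events)
}

#' Simulate the reduced KB PDMP
#'
#' Keeps only the stochastic unbinding events (exponential, rate
#' `theta_b G`); binding events fire deterministically at the first moment
#' of the binding-time distribution, computed by quadrature on
#' `S(t) = exp(-int kappa_b (G_max - G) [A2])` along the current flow.
#' A divergent first moment disables the binding channel.
#'
#' @inheritParams simulate_kb_pdmp
#' @param horizon quadrature horizon for the binding first moment; the
#'   moment is treated as infinite if the survival has not decayed below
#'   `1e-9` by then.
#' @return A `circuit_trajectory` as in [simulate_kb_pdmp()].
#' @export
simulate_kb_reduced <- function(p, init = kb_state_default(), t_end, seed,
                                snapshot_dt = 0.05, horizon = 500) {
  stopifnot(inherits(p, "kb_params"))
  set.seed(seed)
  nms <- c("r_A", "r_I", "A", "A2", "I", "AI")
  cont <- unlist(init[nms])
  G <- init$G
  t_cur <- 0
  rows <- list(c(0, cont))
  discs <- list(G)
  events <- list()

  drift_fn <- function(cont_v, Gv) {
    st <- as.list(c(setNames(cont_v, nms), G = Gv))
    unname(kb_drift(st, p))
  }

  while (t_cur < t_end - 1e-12) {
    t_unb <- if (G > 0 && p$theta_b > 0) rexp(1L, p$theta_b * G) else Inf
    # deterministic binding time: first moment of the binding-time law
    t_bind <- if (G < p$G_max) {
      kb_binding_first_moment(cont, G, p, drift_fn, horizon)
    } else Inf
    dt_ev <- min(t_unb, t_bind)
    seg_end <- min(t_end, t_cur + dt_ev)
    times <- unique(c(seq(t_cur, seg_end, by = snapshot_dt), seg_end))
    out <- deSolve::ode(y = cont, times = times,
                        func = function(t, yv, parms) {
                          list(drift_fn(pmax(yv, 0), G))
                        }, rtol = 1e-8, atol = 1e-10)
    for (i in 2:nrow(out)) {
      rows[[length(rows) + 1L]] <- out[i, ]
      discs[[length(discs) + 1L]] <- G
    }
    cont <- pmax(unname(out[nrow(out), -1L]), 0)
    t_cur <- seg_end
    if (seg_end >= t_end || !is.finite(dt_ev)) break
    if (t_unb <= t_bind) {
      G <- G - 1L
      events[[length(events) + 1L]] <- list(time = t_cur, event = "unbind")
    } else {
      G <- G + 1L
      events[[length(events) + 1L]] <- list(time = t_cur, event = "bind")
    }
  }
  m <- do.call(rbind, rows)
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- c("time", nms)
  df$G <- as.integer(unlist(discs))
  ev <- tibble::tibble(
    time = vapply(events, function(e) e$time, numeric(1)),
    event = vapply(events, function(e) e$event, character(1))
  )
  df$event <- NA_character_
  if (nrow(ev)) {
    idx <- match(round(ev$time, 12), round(df$time, 12))
    df$event[idx[!is.na(idx)]] <- ev$event[!is.na(idx)]
  }
  new_trajectory(df, engine = "kb_reduced", params = p, seed = seed,
                 events = ev, n_events = nrow(ev))
}

# E[T_bind] = int_0^Inf exp(-H(t)) dt with
# H(t) = int_0^t kappa_b (G_max - G) [A2](t') dt', along the frozen-G flow
kb_binding_first_moment <- function(cont, G, p, drift_fn, horizon) {
  rate_mult <- p$kappa_b * (p$G_max - G)
  if (rate_mult <= 0) return(Inf)
  nms_n <- length(cont)
  func <- function(t, yv, parms) {
    cv <- pmax(yv[seq_len(nms_n)], 0)
    dH <- rate_mult * cv[4L] # [A2]
    dM <- exp(-yv[nms_n + 1L])
    list(c(drift_fn(cv, G), dH, dM))
  }
  root <- function(t, yv, parms) exp(-yv[nms_n + 1L]) - 1e-9
  out <- deSolve::lsodar(y = c(cont, 0, 0), times = c(0, horizon),
                         func = func, rootfunc = root,
                         rtol = 1e-8, atol = 1e-10)
  last <- out[nrow(out), ]
  surv_end <- exp(-last[[nms_n + 2L]])
  if (surv_end > 1e-6) return(Inf) # hazard accumulation effectively bounded
  unname(last[[nms_n + 3L]])
}

#' VKBL-model PDMP drift and switching hazards
#'
#' State: mRNAs `m_A`, `m_R`; activator `A`; inhibitor `R`; complex `C`;
#' binary promoter occupancies `G_A`, `G_R` (bound activator on the A and R
#' promoters).  Transcription of each gene switches between its free and
#' bound rates; A and R associate irreversibly into C, and R is recycled
#' when the A inside C degrades (`d_A C` feeds back to R).  Hazards: the
#' activator binds either free promoter at `kappa_* A` and unbinds at
#' `theta_*`.
#'
#' @param state named list with `m_A, m_R, A, R, C, G_A, G_R`.
#' @param p a [vkbl_params()] object.
#' @return `vkbl_drift()`: named derivative vector; `vkbl_hazards()`: named
#'   vector `c(bind_A, unbind_A, bind_R, unbind_R)`.
#' @export
vkbl_drift <- function(state, p) {
  c(m_A = (if (state$G_A > 0) p$tx_A_bound else p$tx_A_free) -
      p$d_mA * state$m_A,
    m_R = (if (state$G_R > 0) p$tx_R_bound else p$tx_R_free) -
      p$d_mR * state$m_R,
    A = p$tl_A * state$m_A - p$d_A * state$A - p$k_C * state$A * state$R,
    R = p$tl_R * state$m_R - p$d_R * state$R - p$k_C * state$A * state$R +
      p$d_A * state$C,
    C = p$k_C * state$A * state$R - p$d_A * state$C)
}

#' @rdname vkbl_drift
#' @export
vkbl_hazards <- function(state, p) {
  c(bind_A = if (state$G_A == 0L) p$kappa_A * max(state$A, 0) else 0,
    unbind_A = if (state$G_A == 1L) p$theta_A else 0,
    bind_R = if (state$G_R == 0L) p$kappa_R * max(state$A, 0) else 0,
    unbind_R = if (state$G_R == 1L) p$theta_R else 0)
}

vkbl_state_default <- function() {
  list(m_A = 0, m_R = 0, A = 0, R = 0, C = 0, G_A = 0L, G_R = 0L)
}

#' Simulate the VKBL-model PDMP
#'
#' @param p a [vkbl_params()] object.
#' @param init state list as in [vkbl_drift()]; default all-zero.
#' @param t_end horizon.
#' @param seed RNG seed.
#' @param snapshot_dt stored sampling interval.
#' @return A `circuit_trajectory` with the VKBL species columns and the two
#'   promoter occupancies.
#' @export
simulate_vkbl_pdmp <- function(p, init = vkbl_state_default(), t_end, seed,
                               snapshot_dt = 0.05) {
  stopifnot(inherits(p, "vkbl_params"))
  set.seed(seed)
  nms <- c("m_A", "m_R", "A", "R", "C")
  drift <- function(cont, disc) {
    st <- as.list(c(setNames(cont, nms), G_A = disc[1L], G_R = disc[2L]))
    unname(vkbl_drift(st, p))
  }
  hazards <- function(cont, disc) {
    st <- as.list(c(setNames(cont, nms), G_A = disc[1L], G_R = disc[2L]))
    vkbl_hazards(st, p)
  }
  jump <- function(disc, ch) {
    switch(ch,
      bind_A = disc + c(1L, 0L),
      unbind_A = disc - c(1L, 0L),
      bind_R = disc + c(0L, 1L),
      unbind_R = disc - c(0L, 1L))
  }
  res <- sim_pdmp_hybrid(drift, hazards, jump,
                         cont0 = unlist(init[nms]),
                         disc0 = c(init$G_A, init$G_R),
                         t_end = t_end, snapshot_dt = snapshot_dt)
  df <- tibble::as_tibble(as.data.frame(res$cont))
  names(df) <- nms
  df <- dplyr::bind_cols(tibble::tibble(time = res$time), df,
                         tibble::tibble(G_A = as.integer(res$disc[, 1L]),
                                        G_R = as.integer(res$disc[, 2L]),
                                        event = res$event))
  events <- res$events
  if (nrow(events)) {
    events$G_A <- as.integer(res$events_disc[, 1L])
    events$G_R <- as.integer(res$events_disc[, 2L])
  } else {
    events$G_A <- integer(0)
    events$G_R <- integer(0)
  }
  new_trajectory(df, engine = "vkbl_pdmp", params = p, seed = seed,
                 events = events, n_events = res$n_events)
}
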