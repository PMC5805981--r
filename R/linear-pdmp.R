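#' Linear flow of the fast-titration limit
#'
#' In the fast-titration linearization the minority species is titrated away
#' instantaneously, so the single positive concentration obeys the linear ODE
#' `dw/dt = b - delta * w` with net production `b` (possibly negative) and
#' decay `delta > 0`, solved exactly by
#' `w(t) = b/delta + (x0 - b/delta) exp(-delta t)`.
#'
#' @param b net production rate (real; negative while the promoter state
#'   drives net titration).
#' @param delta first-order decay rate (> 0).
#' @param x0 initial concentration (>= 0).
#' @return An object of class `linear_flow`.
#' @export
linear_flow <- function(b, delta, x0) {
  if (!is.numeric(delta) || delta <= 0) {
    abort("`delta` must be > 0.", class = "pdmposc_parameter_error")
  }
  if (x0 < 0) abort("`x0` must be >= 0.", class = "pdmposc_parameter_error")
  structure(list(b = b, delta = delta, x0 = x0), class = "linear_flow")
}

#' @rdname linear_flow
#' @param f a [linear_flow()].
#' @param t time (>= 0); vectorized.
#' @return `closed_flow()`: the exact solution w(t); `flow_integral()`: the
#'   exact integral of w over `[0, t]`.
#' @export
closed_flow <- function(f, t) {
  f$b / f$delta + (f$x0 - f$b / f$delta) * exp(-f$delta * t)
}

#' @rdname linear_flow
#' @export
flow_integral <- function(f, t) {
  (f$b / f$delta) * t +
    (f$x0 - f$b / f$delta) * (1 - exp(-f$delta * t)) / f$delta
}

#' Deterministic titration time: first hitting of zero
#'
#' Time at which the linear flow reaches 0 from above.  A flow with `b < 0`
#' always hits zero at `t* = log(1 + delta x0 / (-b)) / delta`; a flow with
#' `b >= 0` never does (it relaxes towards `b/delta`), except for the
#' degenerate start `x0 = 0`, which returns 0.
#'
#' @param f a [linear_flow()].
#' @return A non-negative time, possibly `Inf`.
#' @export
hitting_time_zero <- function(f) {
  if (f$x0 == 0) {
    if (f$b > 0) return(Inf) else return(0)
  }
  if (f$b >= 0) return(Inf)
  log(1 + f$delta * f$x0 / (-f$b)) / f$delta
}

#' Survival function of the next binding event along a linear flow
#'
#' The binding hazard is `kappa * w(t)` (an inhomogeneous Poisson process),
#' so the probability that no binding occurred by time `t` is
#' `S(t) = exp(-kappa * int_0^t w)`, with the integral in closed form.
#' `S(0) = 1` and S is non-increasing while the flow is non-negative.
#'
#' @param t time(s) >= 0.
#' @param f a [linear_flow()] describing the TF concentration.
#' @param kappa association rate (>= 0).
#' @return Survival probabilities in `[0, 1]`.
#' @export
survival_binding <- function(t, f, kappa) {
  if (kappa < 0) abort("`kappa` must be >= 0.",
                       class = "pdmposc_parameter_error")
  exp(-kappa * flow_integral(f, t))
}

#' Sample a binding time by survival-function inversion
#'
#' Smallest `t` with `S(t) = u` for a uniform draw `u`, found by monotone
#' bracketed root-finding on the cumulative hazard (the bracket is grown
#' geometrically while the flow keeps accumulating hazard).  Returns `Inf`
#' when the total accumulated hazard is bounded and `S(Inf) > u` — possible
#' whenever `b <= 0`, where the flow dies out before binding becomes certain.
#'
#' @param f a [linear_flow()].
#' @param kappa association rate (>= 0).
#' @param u a uniform(0,1) variate (the inverse-transform input).
#' @param tol absolute tolerance of the returned time.
#' @return A binding time in `(0, Inf]`.
#' @export
sample_binding_time <- function(f, kappa, u, tol = 1e-10) {
  if (!(u > 0 && u < 1)) {
    abort("`u` must lie strictly in (0, 1).",
          class = "pdmposc_parameter_error")
  }
  target <- -log(u) # solve kappa * I(t) = target
  if (kappa <= 0) return(Inf)
  # supremum of the accumulated hazard
  if (f$b > 0) {
    I_sup <- Inf
  } else if (f$b == 0) {
    I_sup <- f$x0 / f$delta
  } else {
    tstar <- hitting_time_zero(f)
    I_sup <- flow_integral(f, tstar)
  }
  if (kappa * I_sup <= target) return(Inf)
  g <- function(t) kappa * flow_integral(f, t) - target
  upper <- 1 / f$delta
  while (g(upper) < 0) upper <- upper * 2
  uniroot(g, c(0, upper), tol = tol)$root
}

#' Net production rate in the linearized two-regime state space
#'
#' With instantaneous titration of the minority species, the positive
#' species grows at the difference of the two production rates: in the
#' x-positive regime `b = beta_X(s_X) - beta_Y(s_Y)`, in the y-positive
#' regime `b = beta_Y(s_Y) - beta_X(s_X)`.
#'
#' @param s_X,s_Y promoter occupancies.
#' @param p a [titration_params()] object.
#' @param regime `"X"` or `"Y"`.
#' @return Net production rate (real, possibly negative).
#' @export
net_production <- function(s_X, s_Y, p, regime = c("X", "Y")) {
  regime <- match.arg(regime)
  bx <- production_rate(s_X, "X", p)
  by <- production_rate(s_Y, "Y", p)
  if (regime == "X") bx - by else by - bx
}

#' Simulate the linearized PDMP
#'
#' Event loop of the fast-titration linearization: from each state the next
#' event is the earliest of (i) promoter unbinding, exponential with rate
#' `theta_Z`; (ii) promoter binding, sampled by inverting the analytic
#' survival function of the hazard `kappa_Z x(t)` along the current linear
#' flow (zero throughout the y-positive regime, where x = 0); and (iii) the
#' deterministic regime switch when the positive species is titrated to zero.
#' Simultaneous events (probability zero) resolve in the order
#' switch > unbinding > binding.
#'
#' @param p a [titration_params()] object with exactly one regulated gene.
#' @param init a [regime_state()]; default x-positive, `w = 0`, empty
#'   promoter.
#' @param t_end simulation horizon (> 0).
#' @param seed integer RNG seed.
#' @param snapshot_dt sampling interval of the stored trajectory.
#' @return A `circuit_trajectory` tibble (`time, x, y, s_X, s_Y, event`)
#'   where the regime is implicit in which of `x`, `y` is positive; the
#'   `events` attribute stores every transition, including the deterministic
#'   `titration_switch` instants.
#' @examples
#' p <- atc_params(lam = 1, nb = 1)
#' traj <- simulate_linear_pdmp(p, t_end = 100, seed = 1)
#' @export
simulate_linear_pdmp <- function(p, init = regime_state("X", 0, 0L, 0L),
                                 t_end, seed, snapshot_dt = 0.01) {
  stopifnot(inherits(p, "titration_params"), t_end > 0)
  gene <- regulated_gene(p)
  if (is.na(gene)) {
    abort("the linearized PDMP needs a regulated gene (nb > 0).",
          class = "pdmposc_parameter_error")
  }
  kappa <- if (gene == "X") p$kappa_X else p$kappa_Y
  theta <- if (gene == "X") p$theta_X else p$theta_Y
  nb <- if (gene == "X") p$nb_X else p$nb_Y
  set.seed(seed)

  regime <- init$regime
  w <- init$w
  s_X <- init$s_X
  s_Y <- init$s_Y
  check_state_bounds(s_X, s_Y, p)
  t_cur <- 0

  segs <- list() # t0, t1, b, delta, w0, regime, s_X, s_Y, event at t1
  n_seg <- 0L
  push_seg <- function(t1, event) {
    n_seg <<- n_seg + 1L
    segs[[n_seg]] <<- list(t0 = t_cur, t1 = t1, b = b, delta = delta,
                           w0 = w, regime = regime, s_X = s_X, s_Y = s_Y,
                           event = event)
  }

  while (t_cur < t_end) {
    b <- net_production(s_X, s_Y, p, regime)
    delta <- if (regime == "X") p$delta_X else p$delta_Y
    flow <- linear_flow(b, delta, w)
    s <- if (gene == "X") s_X else s_Y

    t_switch <- if (b == 0 && w == 0) Inf else hitting_time_zero(flow)
    t_unbind <- if (s > 0L && theta > 0) rexp(1L, theta) else Inf
    t_bind <- if (s < nb && regime == "X" && kappa > 0) {
      sample_binding_time(flow, kappa, runif_pos(1L))
    } else Inf

    # tie-break order: deterministic switch > unbinding > binding
    dt_ev <- min(t_switch, t_unbind, t_bind)
    winner <- if (t_switch <= dt_ev) "switch"
      else if (t_unbind <= dt_ev) "unbind"
      else "bind"

    if (!is.finite(dt_ev) || t_cur + dt_ev >= t_end) {
      push_seg(t_end, NA_character_)
      t_cur <- t_end
      break
    }

    t_next <- t_cur + dt_ev
    if (winner == "switch") {
      push_seg(t_next, "titration_switch")
      w <- 0
      # the opposite regime has net production -b > 0
      regime <- if (regime == "X") "Y" else "X"
    } else if (winner == "unbind") {
      lbl <- paste0("unbind_", gene)
      push_seg(t_next, lbl)
      w <- closed_flow(flow, dt_ev)
      if (gene == "X") s_X <- s_X - 1L else s_Y <- s_Y - 1L
    } else {
      lbl <- paste0("bind_", gene)
      push_seg(t_next, lbl)
      w <- closed_flow(flow, dt_ev)
      if (gene == "X") s_X <- s_X + 1L else s_Y <- s_Y + 1L
    }
    w <- max(w, 0)
    t_cur <- t_next
  }

  # materialize snapshots on the global grid plus all event instants
  grid <- seq(0, t_end, by = snapshot_dt)
  rows <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    sg <- segs[[i]]
    tt <- grid[grid >= sg$t0 & grid < sg$t1]
    if (i == 1L && (length(tt) == 0L || tt[1L] > sg$t0)) tt <- c(sg$t0, tt)
    tt <- c(tt, sg$t1)
    fl <- linear_flow(sg$b, sg$delta, sg$w0)
    wv <- pmax(closed_flow(fl, tt - sg$t0), 0)
    rows[[i]] <- tibble::tibble(
      time = tt,
      x = if (sg$regime == "X") wv else 0,
      y = if (sg$regime == "Y") wv else 0,
      s_X = sg$s_X, s_Y = sg$s_Y,
      event = c(rep(NA_character_, length(tt) - 1L), sg$event)
    )
  }
  df <- dplyr::bind_rows(rows)
  # event log with POST-event promoter occupancies (next segment's state)
  has_ev <- vapply(segs, function(sg) !is.na(sg$event), logical(1))
  idx <- which(has_ev)
  events <- tibble::tibble(
    time = vapply(segs[idx], `[[`, numeric(1), "t1"),
    event = vapply(segs[idx], `[[`, character(1), "event"),
    s_X = vapply(idx, function(i) {
      if (i < n_seg) segs[[i + 1L]]$s_X else s_X
    }, integer(1)),
    s_Y = vapply(idx, function(i) {
      if (i < n_seg) segs[[i + 1L]]$s_Y else s_Y
    }, integer(1))
  )
  new_trajectory(df, engine = "linear_pdmp", params = p, seed = seed,
                 events = events, n_events = nrow(events))
}
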