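#' Mean waiting times of the linearized-PDMP channels
#'
#' First moments of the competing waiting times out of a linearized state:
#' unbinding is exponential with mean `1/theta_Z`; the binding time has mean
#' `int_0^Inf S(t) dt` (adaptive quadrature on the analytic survival
#' function, `Inf` when the accumulated hazard stays bounded); the
#' deterministic titration time is the flow's hitting time of zero.
#'
#' @param state a [regime_state()].
#' @param p a [titration_params()] object with one regulated gene.
#' @return A tibble with columns `channel` (`"bind"`, `"unbind"`,
#'   `"titration_switch"`) and `mean_time` (possibly `Inf`).
#' @export
mean_waiting_times <- function(state, p) {
  gene <- regulated_gene(p)
  if (is.na(gene)) {
    abort("needs a regulated gene (nb > 0).",
          class = "pdmposc_parameter_error")
  }
  kappa <- if (gene == "X") p$kappa_X else p$kappa_Y
  theta <- if (gene == "X") p$theta_X else p$theta_Y
  nb <- if (gene == "X") p$nb_X else p$nb_Y
  s <- if (gene == "X") state$s_X else state$s_Y
  b <- net_production(state$s_X, state$s_Y, p, state$regime)
  delta <- if (state$regime == "X") p$delta_X else p$delta_Y
  flow <- linear_flow(b, delta, state$w)

  t_switch <- if (b == 0 && state$w == 0) Inf else hitting_time_zero(flow)
  t_unbind <- if (s > 0L && theta > 0) 1 / theta else Inf
  t_bind <- if (s < nb && state$regime == "X" && kappa > 0) {
    mean_binding_time(flow, kappa)
  } else Inf

  tibble::tibble(
    channel = c("bind", "unbind", "titration_switch"),
    mean_time = c(t_bind, t_unbind, t_switch)
  )
}

# E[T_bind] = int_0^Inf S(t) dt; finite only when S decays to 0 (b > 0)
mean_binding_time <- function(f, kappa) {
  if (kappa <= 0) return(Inf)
  if (f$b <= 0) {
    # hazard accumulation is bounded: S(Inf) > 0, infinite mean
    return(Inf)
  }
  integrate(function(t) survival_binding(t, f, kappa), 0, Inf,
            rel.tol = 1e-10)$value
}

#' Alternative deterministic limit (ADL) of the linearized PDMP
#'
#' Replaces every random waiting time by its first moment and, when several
#' channels compete, fires the one with the minimal mean waiting time (a
#' deterministic analogue of the first-reaction method).  The dynamics are
#' fully deterministic: after the first return to a previously visited
#' state the system is exactly periodic with zero period variance.
#'
#' @param p a [titration_params()] object with one regulated gene.
#' @param init a [regime_state()].
#' @param n_cycles number of periods to traverse after periodicity is
#'   detected (the trajectory covers them).
#' @param max_events safety bound on the number of events before a cycle
#'   must have been found.
#' @param snapshot_dt sampling interval of the returned trajectory.
#' @return A `circuit_trajectory` with attributes `period` (the exact cycle
#'   length), `cycle_states` (tibble of the visited states around one
#'   cycle), and `events`.
#' @examples
#' res <- simulate_adl(atc_params(lam = 1, nb = 1))
#' attr(res, "period")
#' @export
simulate_adl <- function(p, init = regime_state("X", 0, 0L, 0L),
                         n_cycles = 3, max_events = 500,
                         snapshot_dt = 0.01) {
  stopifnot(inherits(p, "titration_params"))
  gene <- regulated_gene(p)
  if (is.na(gene)) {
    abort("needs a regulated gene (nb > 0).",
          class = "pdmposc_parameter_error")
  }
  state <- init
  t_cur <- 0
  seen <- character(0)
  seen_times <- numeric(0)
  key_of <- function(st) {
    paste(st$regime, st$s_X, st$s_Y, format(round(st$w, 9), nsmall = 9),
          sep = "|")
  }
  segs <- list()
  period <- NA_real_
  first_rep_key <- NULL
  cycles_done <- 0

  for (i in seq_len(max_events)) {
    key <- key_of(state)
    hit <- which(seen == key)
    if (length(hit) && is.na(period)) {
      period <- t_cur - seen_times[hit[1L]]
      first_rep_key <- key
    } else if (!is.na(period) && identical(key, first_rep_key)) {
      cycles_done <- cycles_done + 1
      if (cycles_done >= n_cycles) break
    }
    seen <- c(seen, key)
    seen_times <- c(seen_times, t_cur)

    mwt <- mean_waiting_times(state, p)
    dt_ev <- min(mwt$mean_time)
    if (!is.finite(dt_ev)) {
      abort("ADL reached an absorbing state: all mean waiting times are infinite (non-oscillatory parameters).",
            class = "pdmposc_simulation_error")
    }
    winner <- mwt$channel[which.min(mwt$mean_time)]
    b <- net_production(state$s_X, state$s_Y, p, state$regime)
    delta <- if (state$regime == "X") p$delta_X else p$delta_Y
    flow <- linear_flow(b, delta, state$w)
    segs[[length(segs) + 1L]] <- list(
      t0 = t_cur, t1 = t_cur + dt_ev, b = b, delta = delta, w0 = state$w,
      regime = state$regime, s_X = state$s_X, s_Y = state$s_Y,
      event = winner
    )
    w_new <- max(closed_flow(flow, dt_ev), 0)
    if (winner == "titration_switch") {
      state <- regime_state(if (state$regime == "X") "Y" else "X", 0,
                            state$s_X, state$s_Y)
    } else {
      ds <- if (winner == "bind") 1L else -1L
      if (gene == "X") {
        state <- regime_state(state$regime, w_new, state$s_X + ds, state$s_Y)
      } else {
        state <- regime_state(state$regime, w_new, state$s_X, state$s_Y + ds)
      }
    }
    t_cur <- t_cur + dt_ev
  }
  if (is.na(period)) {
    abort("no deterministic cycle found within the event budget.",
          class = "pdmposc_simulation_error")
  }

  grid_end <- t_cur
  grid <- seq(0, grid_end, by = snapshot_dt)
  rows <- vector("list", length(segs))
  for (i in seq_along(segs)) {
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
  events <- df |> dplyr::filter(!is.na(.data$event)) |>
    dplyr::select("time", "event", "s_X", "s_Y")
  cycle_states <- tibble::tibble(
    regime = vapply(segs, `[[`, character(1), "regime"),
    s_X = vapply(segs, function(s) as.integer(s$s_X), integer(1)),
    s_Y = vapply(segs, function(s) as.integer(s$s_Y), integer(1)),
    duration = vapply(segs, function(s) s$t1 - s$t0, numeric(1)),
    event = vapply(segs, `[[`, character(1), "event")
  )
  new_trajectory(df, engine = "adl", params = p, seed = NA_integer_,
                 events = events, n_events = nrow(events),
                 period = period, cycle_states = cycle_states)
}
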