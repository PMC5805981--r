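# Generic hybrid kinetic Monte Carlo core shared by the idealized circuit,
# KB and VKBL engines.
#
# Between jumps the continuous state follows `drift`; the event clock is the
# integrated total hazard Lambda(t) = int sum(hazards) dt, augmented as an
# extra ODE state and inverted by lsodar root-finding against a threshold
# -log(u), which is exact for time-inhomogeneous hazards.  The jump channel
# is chosen with probabilities proportional to the hazards evaluated at the
# located event time.
sim_pdmp_hybrid <- function(drift, hazards, jump, cont0, disc0, t_end,
                            snapshot_dt = 0.01, rtol = 1e-8, atol = 1e-10,
                            neg_tol = 1e-8, max_events = 1e6,
                            chunk = 25) {
  nc <- length(cont0)
  cont <- cont0
  disc <- disc0
  t_cur <- 0
  grid <- seq(0, t_end, by = snapshot_dt)

  func <- function(t, yv, parms) {
    cv <- pmax(yv[seq_len(nc)], 0)
    list(c(drift(cv, disc), sum(hazards(cv, disc))))
  }

  seg_rows <- list()
  seg_disc <- list()
  events <- list()
  n_events <- 0L
  add_rows <- function(m, event_label) {
    if (nrow(m) > 0L) {
      seg_rows[[length(seg_rows) + 1L]] <<- m
      seg_disc[[length(seg_disc) + 1L]] <<-
        matrix(rep(disc, each = nrow(m)), nrow = nrow(m))
    }
    if (!is.null(event_label)) {
      events[[length(events) + 1L]] <<-
        list(time = t_cur, channel = event_label)
    }
  }
  # initial row
  add_rows(matrix(c(t_cur, cont), nrow = 1), NULL)

  thr <- -log(runif_pos(1))
  L <- 0
  while (t_cur < t_end - 1e-12) {
    chunk_end <- min(t_end, t_cur + chunk)
    times <- c(t_cur, grid[grid > t_cur + 1e-12 & grid < chunk_end - 1e-12],
               chunk_end)
    out <- deSolve::lsodar(
      y = c(cont, L), times = times, func = func,
      rootfunc = function(t, yv, parms) yv[nc + 1L] - thr,
      rtol = rtol, atol = atol
    )
    last <- out[nrow(out), ]
    new_cont <- unname(last[1L + seq_len(nc)])
    if (any(new_cont < -neg_tol)) {
      abort(paste0("PDMP integration produced a negative concentration (",
                   paste(signif(new_cont, 6), collapse = ", "), ") at t = ",
                   signif(last[1L], 8)),
            class = "pdmposc_simulation_error")
    }
    new_cont <- pmax(new_cont, 0)
    rooted <- last[[1L]] < chunk_end - 1e-10 ||
      abs(last[[nc + 2L]] - thr) <= 1e-6 * max(1, thr)
    rows <- out[-1L, c(1L, 1L + seq_len(nc)), drop = FALSE]
    if (nrow(rows) > 0) {
      rows[, -1L] <- pmax(rows[, -1L, drop = FALSE], 0)
    }
    t_cur <- last[[1L]]
    cont <- new_cont
    if (rooted && t_cur < t_end - 1e-12) {
      h <- hazards(cont, disc)
      h[h < 0] <- 0
      if (sum(h) <= 0) {
        # hazard vanished at the located root (numerical); continue flowing
        add_rows(rows, NULL)
        L <- unname(last[[nc + 2L]])
        next
      }
      ch <- names(h)[sample.int(length(h), 1L, prob = h)]
      add_rows(rows, ch)
      disc <- jump(disc, ch)
      events[[length(events)]]$disc_after <- disc
      n_events <- n_events + 1L
      if (n_events > max_events) {
        abort("PDMP event budget exceeded.",
              class = "pdmposc_simulation_error")
      }
      thr <- -log(runif_pos(1))
      L <- 0
    } else {
      add_rows(rows, NULL)
      L <- unname(last[[nc + 2L]])
    }
  }

  states <- do.call(rbind, seg_rows)
  discm <- do.call(rbind, seg_disc)
  ev_times <- vapply(events, function(e) e$time, numeric(1))
  ev_ch <- vapply(events, function(e) e$channel, character(1))
  ev_disc <- if (length(events)) {
    do.call(rbind, lapply(events, `[[`, "disc_after"))
  } else {
    matrix(numeric(0), ncol = length(disc0))
  }
  event_col <- rep(NA_character_, nrow(states))
  if (length(ev_times)) {
    idx <- match(round(ev_times, 12), round(states[, 1L], 12))
    ok <- !is.na(idx)
    event_col[idx[ok]] <- ev_ch[ok]
  }
  list(time = states[, 1L],
       cont = states[, -1L, drop = FALSE],
       disc = discm,
       event = event_col,
       events = tibble::tibble(time = ev_times, event = ev_ch),
       events_disc = ev_disc,
       n_events = n_events)
}

# runif that never returns an exact 0 (threshold -log(u) must be finite)
runif_pos <- function(n) {
  u <- runif(n)
  while (any(u <= 0)) u[u <= 0] <- runif(sum(u <= 0))
  u
}

#' Hybrid kinetic Monte Carlo simulation of the PDMP
#'
#' Simulates the piecewise deterministic Markov process derived from the
#' titration-circuit CME in the thermodynamic limit: concentrations follow
#' the deterministic drift [pdmp_drift()] between stochastic promoter
#' switching events whose time-inhomogeneous hazards [switching_hazards()]
#' depend on the current concentrations.  Event times are drawn exactly by
#' integrating the cumulative hazard alongside the ODE flow and root-finding
#' its crossing of an exponential threshold.
#'
#' @param p a [titration_params()] object.
#' @param init a [hybrid_state()]; default all-zero.
#' @param t_end simulation horizon (> 0).
#' @param seed integer RNG seed.
#' @param tol ODE relative tolerance and negative-concentration guard
#'   (absolute tolerance is `tol * 0.01`).
#' @param snapshot_dt sampling interval of the stored trajectory; all
#'   switching instants are stored in addition.
#' @return A `circuit_trajectory` tibble (`time, x, y, s_X, s_Y, event`),
#'   with the switching events in the `events` attribute.
#' @examples
#' p <- atc_params(lam = 1, nb = 1)
#' traj <- simulate_pdmp(p, t_end = 50, seed = 1)
#' @export
simulate_pdmp <- function(p, init = hybrid_state(), t_end, seed,
                          tol = 1e-8, snapshot_dt = 0.01) {
  stopifnot(inherits(p, "titration_params"), t_end > 0, tol > 0)
  check_state_bounds(init$s_X, init$s_Y, p)
  set.seed(seed)
  drift <- function(cont, disc) {
    bx <- if (disc[1L] == 0) p$beta_f_X else p$beta_b_X
    by <- if (disc[2L] == 0) p$beta_f_Y else p$beta_b_Y
    tit <- p$alpha * cont[1L] * cont[2L]
    c(bx - p$delta_X * cont[1L] - tit,
      by - p$delta_Y * cont[2L] - tit)
  }
  hazards <- function(cont, disc) {
    hazard_vector(cont[1L], disc[1L], disc[2L], p)
  }
  jump <- function(disc, ch) {
    upd <- apply_promoter_event(disc[1L], disc[2L], ch)
    c(upd$s_X, upd$s_Y)
  }
  res <- sim_pdmp_hybrid(drift, hazards, jump,
                         cont0 = c(init$x, init$y),
                         disc0 = c(init$s_X, init$s_Y),
                         t_end = t_end, snapshot_dt = snapshot_dt,
                         rtol = tol, atol = tol * 1e-2, neg_tol = tol)
  df <- tibble::tibble(
    time = res$time,
    x = res$cont[, 1L],
    y = res$cont[, 2L],
    s_X = as.integer(res$disc[, 1L]),
    s_Y = as.integer(res$disc[, 2L]),
    event = res$event
  )
  events <- res$events
  if (nrow(events)) {
    events$s_X <- as.integer(res$events_disc[, 1L])
    events$s_Y <- as.integer(res$events_disc[, 2L])
  } else {
    events$s_X <- integer(0)
    events$s_Y <- integer(0)
  }
  new_trajectory(df, engine = "pdmp", params = p, seed = seed,
                 events = events, n_events = res$n_events)
}
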