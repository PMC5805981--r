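#' Model states
#'
#' `discrete_state()` holds integer copy numbers and promoter occupancies for
#' the chemical master equation (CME); `hybrid_state()` holds real
#' concentrations plus promoter occupancies for the piecewise deterministic
#' Markov process (PDMP); `regime_state()` is the linearized-PDMP state where
#' exactly one species is positive (`regime` "X" means y = 0, "Y" means
#' x = 0) with concentration `w`.
#'
#' @param N_X,N_Y non-negative integer copy numbers.
#' @param x,y non-negative real concentrations.
#' @param s_X,s_Y promoter occupancies (number of bound X on each promoter).
#' @param regime `"X"` or `"Y"`: which species is positive.
#' @param w concentration of the positive species (>= 0).
#' @return A classed named list.
#' @export
discrete_state <- function(N_X = 0L, N_Y = 0L, s_X = 0L, s_Y = 0L) {
  stopifnot(N_X >= 0, N_Y >= 0, s_X >= 0, s_Y >= 0,
            N_X == round(N_X), N_Y == round(N_Y))
  structure(list(N_X = as.numeric(N_X), N_Y = as.numeric(N_Y),
                 s_X = as.integer(s_X), s_Y = as.integer(s_Y)),
            class = "discrete_state")
}

#' @rdname discrete_state
#' @export
hybrid_state <- function(x = 0, y = 0, s_X = 0L, s_Y = 0L) {
  stopifnot(x >= 0, y >= 0, s_X >= 0, s_Y >= 0)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 s_X = as.integer(s_X), s_Y = as.integer(s_Y)),
            class = "hybrid_state")
}

#' @rdname discrete_state
#' @export
regime_state <- function(regime = c("X", "Y"), w = 0, s_X = 0L, s_Y = 0L) {
  regime <- match.arg(regime)
  stopifnot(w >= 0, s_X >= 0, s_Y >= 0)
  structure(list(regime = regime, w = as.numeric(w),
                 s_X = as.integer(s_X), s_Y = as.integer(s_Y)),
            class = "regime_state")
}

check_state_bounds <- function(s_X, s_Y, p) {
  if (s_X < 0 || s_X > p$nb_X || s_Y < 0 || s_Y > p$nb_Y) {
    abort("promoter occupancy out of [0, nb] bounds.",
          class = "pdmposc_state_error")
  }
  invisible(TRUE)
}

#' Reaction channels and propensities of the full CME
#'
#' Lists every active reaction channel at a discrete state, with its
#' propensity and its effect on `(N_X, N_Y, s_X, s_Y)`.  Mass-action
#' system-size scaling follows reaction order: zeroth-order production has
#' propensity `Omega * beta`, first-order `rate * N`, second-order
#' `rate * N * N' / Omega`.  Binding of X to a promoter consumes one free X
#' molecule; unbinding returns it.  Channels forbidden by the promoter bounds
#' (binding at `s = nb`, unbinding at `s = 0`) are absent.
#'
#' @param state a [discrete_state()].
#' @param p a [titration_params()] object.
#' @return A tibble with columns `label`, `rate`, `dN_X`, `dN_Y`, `ds_X`,
#'   `ds_Y`.
#' @export
cme_channels <- function(state, p) {
  check_state_bounds(state$s_X, state$s_Y, p)
  if (state$N_X < 0 || state$N_Y < 0) {
    abort("copy numbers must be non-negative.", class = "pdmposc_state_error")
  }
  Om <- p$Omega
  ch <- list(
    list("prod_X", Om * production_rate(state$s_X, "X", p), 1, 0, 0, 0),
    list("prod_Y", Om * production_rate(state$s_Y, "Y", p), 0, 1, 0, 0),
    list("deg_X", p$delta_X * state$N_X, -1, 0, 0, 0),
    list("deg_Y", p$delta_Y * state$N_Y, 0, -1, 0, 0),
    list("titration", p$alpha * state$N_X * state$N_Y / Om, -1, -1, 0, 0)
  )
  if (state$s_X < p$nb_X) {
    ch <- c(ch, list(list("bind_X", p$kappa_X * state$N_X / Om, -1, 0, 1, 0)))
  }
  if (state$s_X > 0L) {
    ch <- c(ch, list(list("unbind_X", p$theta_X, 1, 0, -1, 0)))
  }
  if (state$s_Y < p$nb_Y) {
    ch <- c(ch, list(list("bind_Y", p$kappa_Y * state$N_X / Om, -1, 0, 0, 1)))
  }
  if (state$s_Y > 0L) {
    ch <- c(ch, list(list("unbind_Y", p$theta_Y, 1, 0, 0, -1)))
  }
  tibble::tibble(
    label = vapply(ch, `[[`, character(1), 1L),
    rate = vapply(ch, `[[`, numeric(1), 2L),
    dN_X = vapply(ch, `[[`, numeric(1), 3L),
    dN_Y = vapply(ch, `[[`, numeric(1), 4L),
    ds_X = vapply(ch, `[[`, numeric(1), 5L),
    ds_Y = vapply(ch, `[[`, numeric(1), 6L)
  )
}

#' Deterministic drift field of the PDMP
#'
#' Lowest-order (thermodynamic-limit) flow of the concentrations between
#' promoter-switching events: production at the current promoter state,
#' first-order degradation, and bimolecular titration.  The O(1/Omega)
#' promoter-sequestration flux is omitted, consistent with the lowest-order
#' system-size expansion.
#'
#' @param state a [hybrid_state()].
#' @param p a [titration_params()] object.
#' @return Named numeric vector `c(dx, dy)`.
#' @export
pdmp_drift <- function(state, p) {
  check_state_bounds(state$s_X, state$s_Y, p)
  bx <- production_rate(state$s_X, "X", p)
  by <- production_rate(state$s_Y, "Y", p)
  tit <- p$alpha * state$x * state$y
  c(dx = bx - p$delta_X * state$x - tit,
    dy = by - p$delta_Y * state$y - tit)
}

#' Promoter-switching hazards of the PDMP
#'
#' The Markovian switching part of the PDMP generator: for each regulated
#' gene Z, sequential binding `s_Z -> s_Z + 1` at rate `kappa_Z * x` (when
#' `s_Z < nb_Z`) and unbinding `s_Z -> s_Z - 1` at rate `theta_Z` (when
#' `s_Z > 0`).  The binder is always the TF X, so hazards depend on `x` only.
#'
#' @param state a [hybrid_state()].
#' @param p a [titration_params()] object.
#' @return A tibble with columns `channel`, `gene`, `rate`.
#' @export
switching_hazards <- function(state, p) {
  check_state_bounds(state$s_X, state$s_Y, p)
  h <- list()
  if (state$s_X < p$nb_X) {
    h <- c(h, list(list("bind_X", "X", p$kappa_X * state$x)))
  }
  if (state$s_X > 0L) h <- c(h, list(list("unbind_X", "X", p$theta_X)))
  if (state$s_Y < p$nb_Y) {
    h <- c(h, list(list("bind_Y", "Y", p$kappa_Y * state$x)))
  }
  if (state$s_Y > 0L) h <- c(h, list(list("unbind_Y", "Y", p$theta_Y)))
  tibble::tibble(
    channel = vapply(h, `[[`, character(1), 1L),
    gene = vapply(h, `[[`, character(1), 2L),
    rate = vapply(h, `[[`, numeric(1), 3L)
  )
}

# hazards as a plain named vector for the simulation engines
hazard_vector <- function(x, s_X, s_Y, p) {
  c(bind_X = if (s_X < p$nb_X) p$kappa_X * x else 0,
    unbind_X = if (s_X > 0L) p$theta_X else 0,
    bind_Y = if (s_Y < p$nb_Y) p$kappa_Y * x else 0,
    unbind_Y = if (s_Y > 0L) p$theta_Y else 0)
}

apply_promoter_event <- function(s_X, s_Y, channel) {
  switch(channel,
    bind_X = list(s_X = s_X + 1L, s_Y = s_Y),
    unbind_X = list(s_X = s_X - 1L, s_Y = s_Y),
    bind_Y = list(s_X = s_X, s_Y = s_Y + 1L),
    unbind_Y = list(s_X = s_X, s_Y = s_Y - 1L),
    abort(paste0("unknown switching channel: ", channel))
  )
}
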