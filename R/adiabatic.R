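#' Quasi-stationary distribution of promoter occupancy
#'
#' In the fast-switching (adiabatic) limit the TF concentration `x` is
#' quasi-frozen and the sequential promoter is a one-dimensional birth-death
#' chain with constant birth rate `kappa_Z x` and death rate `theta_Z`; its
#' stationary law by detailed balance is `pi_s ∝ (kappa_Z x / theta_Z)^s`,
#' `s = 0..nb`.  With `theta_Z = 0` and positive binding the chain is
#' absorbed at full occupancy, returned as a point mass at `s = nb`.
#'
#' @param x TF concentration (>= 0).
#' @param p a [titration_params()] object.
#' @param gene `"X"` or `"Y"` — which promoter.
#' @return A tibble with columns `s` (0..nb) and `prob` (sums to 1).
#' @export
promoter_qsd <- function(x, p, gene = c("X", "Y")) {
  gene <- match.arg(gene)
  if (x < 0) abort("`x` must be >= 0.", class = "pdmposc_parameter_error")
  nb <- if (gene == "X") p$nb_X else p$nb_Y
  kappa <- if (gene == "X") p$kappa_X else p$kappa_Y
  theta <- if (gene == "X") p$theta_X else p$theta_Y
  s <- 0:nb
  if (nb == 0L) {
    probs <- 1
  } else if (theta == 0 && kappa * x > 0) {
    probs <- c(rep(0, nb), 1) # degenerate: absorbed at s = nb
  } else if (kappa * x == 0) {
    probs <- c(1, rep(0, nb))
  } else {
    r <- kappa * x / theta
    w <- r^s
    probs <- w / sum(w)
  }
  tibble::tibble(s = s, prob = probs)
}

#' Effective production rate in the adiabatic limit
#'
#' Promoter-averaged production under the quasi-stationary distribution:
#' `beta_f * pi_0 + beta_b * (1 - pi_0)`.  Vectorized over `x`.
#'
#' @param x TF concentration(s) (>= 0).
#' @inheritParams promoter_qsd
#' @return Effective production rate(s).
#' @export
effective_production <- function(x, p, gene = c("X", "Y")) {
  gene <- match.arg(gene)
  bf <- if (gene == "X") p$beta_f_X else p$beta_f_Y
  bb <- if (gene == "X") p$beta_b_X else p$beta_b_Y
  vapply(x, function(xi) {
    pi0 <- promoter_qsd(xi, p, gene)$prob[1L]
    bf * pi0 + bb * (1 - pi0)
  }, numeric(1))
}

# d/dx of the effective production rate, analytic.
# pi_0 = 1 / g(r) with g(r) = sum_{s=0}^{nb} r^s, r = kappa x / theta;
# d beta_eff/dx = (bb - bf) * g'(r)/g(r)^2 * kappa/theta.
effective_production_slope <- function(x, p, gene = c("X", "Y")) {
  gene <- match.arg(gene)
  nb <- if (gene == "X") p$nb_X else p$nb_Y
  kappa <- if (gene == "X") p$kappa_X else p$kappa_Y
  theta <- if (gene == "X") p$theta_X else p$theta_Y
  bf <- if (gene == "X") p$beta_f_X else p$beta_f_Y
  bb <- if (gene == "X") p$beta_b_X else p$beta_b_Y
  if (nb == 0L || kappa == 0 || theta == 0) return(rep(0, length(x)))
  r <- kappa * x / theta
  s <- 0:nb
  g <- vapply(r, function(ri) sum(ri^s), numeric(1))
  gp <- vapply(r, function(ri) sum(s * ri^pmax(s - 1, 0) * (s > 0)),
               numeric(1))
  (bb - bf) * gp / g^2 * kappa / theta
}

#' Mass-action ODEs of the adiabatic limit
#'
#' The deterministic rate equations obtained by replacing the promoter state
#' with its quasi-stationary average: `dx/dt = beta_eff_X(x) - delta_X x -
#' alpha x y`, `dy/dt = beta_eff_Y(x) - delta_Y y - alpha x y`.  For the ATC
#' the X gene is constitutive (`beta_eff_X` constant); for the RTC the Y
#' gene is.
#'
#' @param x,y concentrations.
#' @param p a [titration_params()] object.
#' @return Named numeric vector `c(dx, dy)`.
#' @export
adiabatic_rhs <- function(x, y, p) {
  tit <- p$alpha * x * y
  c(dx = effective_production(x, p, "X") - p$delta_X * x - tit,
    dy = effective_production(x, p, "Y") - p$delta_Y * y - tit)
}

#' Integrate the adiabatic mass-action ODEs
#'
#' @param p a [titration_params()] object.
#' @param init length-2 vector `c(x, y)` of non-negative initial
#'   concentrations.
#' @param t_end horizon.
#' @param dt output sampling interval.
#' @return A `circuit_trajectory` tibble (promoter columns carry the
#'   quasi-stationary mean occupancy is not tracked; `s_X = s_Y = NA`).
#' @export
simulate_adiabatic <- function(p, init = c(x = 0, y = 0), t_end, dt = 0.05) {
  func <- function(t, yv, parms) list(adiabatic_rhs(yv[1L], yv[2L], p))
  out <- deSolve::ode(y = unname(init), times = seq(0, t_end, by = dt),
                      func = func, rtol = 1e-8, atol = 1e-10)
  df <- tibble::tibble(time = out[, 1L], x = out[, 2L], y = out[, 3L],
                       s_X = NA_integer_, s_Y = NA_integer_,
                       event = NA_character_)
  new_trajectory(df, engine = "adiabatic_ode", params = p, seed = NA_integer_)
}

#' Trace of the Jacobian of the adiabatic ODEs
#'
#' `tr J = d beta_eff_X/dx - delta_X - delta_Y - alpha (x + y)`.  The
#' derivative is analytic from the quasi-stationary distribution.
#'
#' @param x,y concentrations.
#' @param p a [titration_params()] object.
#' @return The trace (scalar, vectorized over equal-length `x`, `y`).
#' @export
jacobian_trace <- function(x, y, p) {
  effective_production_slope(x, p, "X") - p$delta_X - p$delta_Y -
    p$alpha * (x + y)
}

#' Bendixson no-limit-cycle certificate
#'
#' Evaluates the Jacobian trace of the adiabatic ODEs on a rectangular grid
#' over the biologically relevant quadrant; if the trace is strictly
#' negative everywhere, the Bendixson criterion rules out deterministic
#' limit cycles in that region.  This is a grid certificate, not a symbolic
#' proof; grid and bounds are configurable.
#'
#' @param p a [titration_params()] object.
#' @param x_max,y_max domain bounds; default `3 * beta_max / delta` with
#'   `beta_max` the largest production rate.
#' @param n_grid grid points per axis.
#' @return A list with `no_limit_cycle` (logical), `worst_trace` (the
#'   maximum trace over the grid) and `worst_point`.
#' @export
no_limit_cycle_check <- function(p, x_max = NULL, y_max = NULL,
                                 n_grid = 200) {
  beta_max <- max(p$beta_f_X, p$beta_b_X, p$beta_f_Y, p$beta_b_Y)
  if (is.null(x_max)) x_max <- 3 * beta_max / p$delta_X
  if (is.null(y_max)) y_max <- 3 * beta_max / p$delta_Y
  xs <- seq(0, x_max, length.out = n_grid)
  ys <- seq(0, y_max, length.out = n_grid)
  # trace is additive in x-terms and y-terms: evaluate on axes, combine
  tx <- effective_production_slope(xs, p, "X") - p$alpha * xs
  ty <- -p$alpha * ys
  worst_x <- which.max(tx)
  worst_y <- which.max(ty)
  worst <- tx[worst_x] + ty[worst_y] - p$delta_X - p$delta_Y
  list(no_limit_cycle = worst < 0,
       worst_trace = worst,
       worst_point = c(x = xs[worst_x], y = ys[worst_y]))
}
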