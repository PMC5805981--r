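#' Period-detection protocol
#'
#' Configuration for [detect_periods()].  The default `"hysteresis"` method
#' records an upward crossing of the observable through `x_hi` only after a
#' prior excursion below `x_lo`; a period is the time between successive
#' qualifying upward crossings.  The hysteresis band rejects
#' promoter-timescale jitter while capturing the alternating high-amplitude
#' phases of the titration circuits.  Thresholds default to fractions of the
#' observable gene's maximal steady level `beta_max / delta` (`x_hi` at 50%,
#' `x_lo` at 5%), where `beta_max` is the larger production rate of the
#' observable's own gene.  The alternative `"promoter"` method measures the
#' time between successive binding events that carry the promoter from fully
#' empty occupancy (`s`: 0 -> 1).
#'
#' @param observable trajectory column to threshold (`"x"` or `"y"` for the
#'   idealized circuits; any species column for the extended models, with
#'   explicit thresholds).
#' @param x_hi,x_lo hysteresis thresholds; `NULL` means derive from the
#'   trajectory's parameter set (only possible for `"x"`/`"y"`).
#' @param min_period periods below this are discarded (with the count
#'   recorded).
#' @param method `"hysteresis"` or `"promoter"`.
#' @return A list of class `period_protocol`.
#' @export
period_protocol <- function(observable = "x", x_hi = NULL, x_lo = NULL,
                            min_period = 0,
                            method = c("hysteresis", "promoter")) {
  method <- match.arg(method)
  stopifnot(is.character(observable), length(observable) == 1L)
  structure(list(observable = observable, x_hi = x_hi, x_lo = x_lo,
                 min_period = min_period, method = method),
            class = "period_protocol")
}

resolve_protocol <- function(protocol, params) {
  if (protocol$method == "promoter") return(protocol)
  if (is.null(protocol$x_hi) || is.null(protocol$x_lo)) {
    if (is.null(params) || !inherits(params, "titration_params") ||
        !protocol$observable %in% c("x", "y")) {
      abort("protocol thresholds not given and they cannot be derived for this trajectory/observable.",
            class = "pdmposc_parameter_error")
    }
    if (protocol$observable == "x") {
      beta_max <- max(params$beta_f_X, params$beta_b_X)
      delta <- params$delta_X
    } else {
      beta_max <- max(params$beta_f_Y, params$beta_b_Y)
      delta <- params$delta_Y
    }
    lvl <- beta_max / delta
    if (is.null(protocol$x_hi)) protocol$x_hi <- 0.5 * lvl
    if (is.null(protocol$x_lo)) protocol$x_lo <- 0.05 * lvl
  }
  if (protocol$x_lo >= protocol$x_hi) {
    abort("`x_lo` must be below `x_hi`.", class = "pdmposc_parameter_error")
  }
  protocol
}

#' Detect stochastic cycle periods in a trajectory
#'
#' Applies a [period_protocol()] to a simulated trajectory and returns the
#' sample of cycle periods.  Crossing times are linearly interpolated
#' between stored samples.
#'
#' @param traj a `circuit_trajectory` (any engine).
#' @param protocol a [period_protocol()].
#' @return A `period_sample` object; see [tidy()]/[glance()] methods.
#' @examples
#' traj <- simulate_linear_pdmp(atc_params(), t_end = 200, seed = 1)
#' glance(detect_periods(traj))
#' @export
detect_periods <- function(traj, protocol = period_protocol()) {
  protocol <- resolve_protocol(protocol, attr(traj, "params"))
  if (protocol$method == "promoter") {
    ev <- attr(traj, "events")
    if (is.null(ev)) {
      abort("trajectory carries no event log; the promoter protocol needs un-thinned promoter-change times.",
            class = "pdmposc_trajectory_error")
    }
    # onset = binding event that takes the promoter from empty to occupied
    occ_after <- if (all(c("s_X", "s_Y") %in% names(ev))) {
      ev$s_X + ev$s_Y
    } else if ("G" %in% names(ev)) {
      ev$G
    } else if (all(c("G_A", "G_R") %in% names(ev))) {
      ev$G_A + ev$G_R
    } else {
      abort("event log carries no promoter-occupancy columns.",
            class = "pdmposc_trajectory_error")
    }
    crossings <- ev$time[grepl("^bind", ev$event) & occ_after == 1L]
  } else {
    obs <- traj[[protocol$observable]]
    tt <- traj$time
    crossings <- hysteresis_crossings(tt, obs, protocol$x_hi, protocol$x_lo)
  }
  periods <- diff(crossings)
  sample <- new_period_sample(periods, n_discarded = 0L, protocol = protocol)
  if (protocol$min_period > 0) {
    sample <- period_filter(sample, protocol$min_period)
  }
  if (length(sample$periods) < 1L) {
    warn("fewer than 2 qualifying crossings: empty period sample.")
  }
  sample
}

# upward crossings of hi qualifying only after an excursion below lo,
# with linear interpolation of the crossing time
hysteresis_crossings <- function(tt, obs, hi, lo) {
  n <- length(obs)
  if (n < 2L) return(numeric(0))
  up <- which(obs[-n] < hi & obs[-1L] >= hi)
  below <- which(obs <= lo)
  if (!length(up) || !length(below)) return(numeric(0))
  crossings <- numeric(0)
  last_qualified <- 0L
  for (i in up) {
    # most recent below-lo sample at or before i
    k <- below[findInterval(i, below)]
    if (!is.na(k) && length(k) && k > last_qualified) {
      t_cross <- tt[i] + (hi - obs[i]) / (obs[i + 1L] - obs[i]) *
        (tt[i + 1L] - tt[i])
      crossings <- c(crossings, t_cross)
      last_qualified <- i
    }
  }
  crossings
}

#' Period sample
#'
#' Container for detected stochastic-cycle periods with summary statistics.
#' `tidy()` returns one row per period; `glance()` returns a one-row summary
#' with `n`, `mean`, `variance` (unbiased), `cv = sd/mean`, a bootstrap
#' standard error of the CV, and the discarded-period count.
#'
#' @param periods positive cycle lengths.
#' @param n_discarded count removed by the minimum-period filter.
#' @param protocol the protocol that produced the sample.
#' @return An object of class `period_sample`.
#' @keywords internal
new_period_sample <- function(periods, n_discarded = 0L, protocol = NULL) {
  structure(list(periods = as.numeric(periods),
                 n_discarded = as.integer(n_discarded),
                 protocol = protocol),
            class = "period_sample")
}

#' Discard periods below a minimum length
#'
#' Mirrors the analysis practice of removing sub-threshold "mini-cycles"
#' before summarizing period statistics; the number removed is recorded.
#'
#' @param sample a `period_sample`.
#' @param min_period threshold; periods strictly below it are removed.
#' @return A filtered `period_sample` with `n_discarded` incremented.
#' @export
period_filter <- function(sample, min_period) {
  stopifnot(inherits(sample, "period_sample"))
  keep <- sample$periods >= min_period
  new_period_sample(sample$periods[keep],
                    n_discarded = sample$n_discarded + sum(!keep),
                    protocol = sample$protocol)
}

#' @rdname new_period_sample
#' @param x a `period_sample`.
#' @param ... unused.
#' @export
tidy.period_sample <- function(x, ...) {
  tibble::tibble(period = x$periods)
}

#' @rdname new_period_sample
#' @param n_boot bootstrap resamples for the CV standard error (0 disables).
#' @export
glance.period_sample <- function(x, n_boot = 1000, ...) {
  n <- length(x$periods)
  m <- mean(x$periods)
  v <- if (n > 1L) var(x$periods) else NA_real_
  cv <- sqrt(v) / m
  cv_se <- NA_real_
  if (n_boot > 0 && n > 1L) {
    bo <- vapply(seq_len(n_boot), function(i) {
      s <- x$periods[sample.int(n, n, replace = TRUE)]
      sd(s) / mean(s)
    }, numeric(1))
    cv_se <- sd(bo)
  }
  tibble::tibble(n = n, mean = m, variance = v, cv = cv, cv_se = cv_se,
                 n_discarded = x$n_discarded)
}

#' @export
print.period_sample <- function(x, ...) {
  g <- glance(x, n_boot = 0)
  cat("<period_sample> n =", g$n, " mean =", signif(g$mean, 4),
      " cv =", signif(g$cv, 4), " (", x$n_discarded, "discarded )\n")
  invisible(x)
}

#' @rdname new_period_sample
#' @param object a `period_sample`.
#' @param bins histogram bins.
#' @export
autoplot.period_sample <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$period)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "period", y = "density") +
    ggplot2::theme_minimal()
}

#' Hypoexponential period law of a two-state promoter
#'
#' A promoter cycling between two states with constant rates `k_plus`
#' (on-switching) and `k_minus` (off-switching) has cycle period equal to
#' the sum of two independent exponentials, i.e. hypoexponentially
#' distributed with density
#' `k_plus k_minus / (k_minus - k_plus) * (exp(-k_plus t) - exp(-k_minus t))`
#' (Erlang-2 `k^2 t exp(-k t)` at equal rates), mean `1/k_plus + 1/k_minus`
#' and variance `1/k_plus^2 + 1/k_minus^2`.
#'
#' @param tau period value(s) (>= 0).
#' @param k_plus,k_minus positive switching rates.
#' @return `hypoexp_pdf()`: densities; `hypoexp_moments()`: a one-row tibble
#'   with `mean`, `variance`, `cv`; `hypoexp_sample()`: `n` sampled periods.
#' @export
hypoexp_pdf <- function(tau, k_plus, k_minus) {
  check_rates(k_plus, k_minus)
  if (isTRUE(all.equal(k_plus, k_minus, tolerance = 1e-9))) {
    k <- (k_plus + k_minus) / 2
    return(ifelse(tau < 0, 0, k^2 * tau * exp(-k * tau)))
  }
  ifelse(tau < 0, 0,
         k_plus * k_minus / (k_minus - k_plus) *
           (exp(-k_plus * tau) - exp(-k_minus * tau)))
}

#' @rdname hypoexp_pdf
#' @export
hypoexp_moments <- function(k_plus, k_minus) {
  check_rates(k_plus, k_minus)
  m <- 1 / k_plus + 1 / k_minus
  v <- 1 / k_plus^2 + 1 / k_minus^2
  tibble::tibble(mean = m, variance = v, cv = sqrt(v) / m)
}

#' @rdname hypoexp_pdf
#' @param n number of samples.
#' @param seed optional RNG seed.
#' @export
hypoexp_sample <- function(n, k_plus, k_minus, seed = NULL) {
  check_rates(k_plus, k_minus)
  if (!is.null(seed)) set.seed(seed)
  rexp(n, k_plus) + rexp(n, k_minus)
}

#' @rdname hypoexp_pdf
#' @param q quantile(s).
#' @export
hypoexp_cdf <- function(q, k_plus, k_minus) {
  check_rates(k_plus, k_minus)
  if (isTRUE(all.equal(k_plus, k_minus, tolerance = 1e-9))) {
    k <- (k_plus + k_minus) / 2
    return(ifelse(q < 0, 0, 1 - exp(-k * q) * (1 + k * q)))
  }
  ifelse(q < 0, 0,
         1 - (k_minus * exp(-k_plus * q) - k_plus * exp(-k_minus * q)) /
           (k_minus - k_plus))
}

check_rates <- function(k_plus, k_minus) {
  if (!is.numeric(k_plus) || !is.numeric(k_minus) ||
      any(k_plus <= 0) || any(k_minus <= 0)) {
    abort("switching rates must be positive.",
          class = "pdmposc_parameter_error")
  }
  invisible(TRUE)
}
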