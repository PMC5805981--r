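#' Run a configured simulation and write its artifacts
#'
#' High-level driver behind the command-line interface: builds the model
#' (preset name, [titration_params()] object, or config file path), runs the
#' requested engine, optionally writes the trajectory CSV (+ JSON metadata
#' sidecar) and a run summary JSON, and returns the trajectory.
#'
#' @param model `"ATC"`, `"RTC"`, a [titration_params()] object, or a path
#'   to a YAML config readable by [read_params()].
#' @param engine one of `"cme"`, `"pdmp"`, `"linear"`, `"adl"`.
#' @param lambda,nb preset adiabaticity scaling and binding-site count
#'   (ignored when `model` is already a parameter object/config).
#' @param t_end simulation horizon (ADL uses `n_cycles` instead).
#' @param seed integer RNG seed; recorded in all outputs.
#' @param n_cycles ADL cycle count.
#' @param snapshot_dt stored sampling interval.
#' @param out_trajectory,out_summary optional output file paths.
#' @param quiet suppress the log line.
#' @return The `circuit_trajectory`, invisibly when files are written.
#' @export
run_simulation <- function(model = "ATC",
                           engine = c("cme", "pdmp", "linear", "adl"),
                           lambda = 1, nb = 1L, t_end = 100, seed = 1L,
                           n_cycles = 3, snapshot_dt = 0.01,
                           out_trajectory = NULL, out_summary = NULL,
                           quiet = FALSE) {
  engine <- match.arg(engine)
  p <- resolve_model(model, lambda, nb)
  t0 <- Sys.time()
  traj <- switch(engine,
    cme = simulate_cme(p, t_end = t_end, seed = seed,
                       snapshot_dt = snapshot_dt),
    pdmp = simulate_pdmp(p, t_end = t_end, seed = seed,
                         snapshot_dt = snapshot_dt),
    linear = simulate_linear_pdmp(p, t_end = t_end, seed = seed,
                                  snapshot_dt = snapshot_dt),
    adl = simulate_adl(p, n_cycles = n_cycles, snapshot_dt = snapshot_dt)
  )
  wall <- as.numeric(Sys.time() - t0, units = "secs")
  if (!quiet) {
    message(sprintf("[pdmposc] engine=%s circuit=%s lambda=%g seed=%s events=%s wall=%.2fs",
                    engine, p$circuit, p$lam, seed,
                    attr(traj, "n_events") %||% NA, wall))
  }
  if (!is.null(out_trajectory)) write_trajectory(traj, out_trajectory)
  if (!is.null(out_summary)) {
    jsonlite::write_json(
      list(engine = engine, params = as_config(p), seed = seed,
           t_end = t_end, n_events = attr(traj, "n_events"),
           period = attr(traj, "period"), wall_seconds = wall),
      out_summary, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (is.null(out_trajectory) && is.null(out_summary)) traj
  else invisible(traj)
}

resolve_model <- function(model, lambda, nb) {
  if (inherits(model, "titration_params")) return(model)
  if (is.character(model) && length(model) == 1L) {
    if (toupper(model) == "ATC") return(atc_params(lam = lambda, nb = nb))
    if (toupper(model) == "RTC") return(rtc_params(lam = lambda, nb = nb))
    if (file.exists(model)) return(read_params(model))
  }
  abort("`model` must be \"ATC\", \"RTC\", a titration_params object or a config path.",
        class = "pdmposc_parameter_error")
}

#' Sweep period statistics over a parameter grid
#'
#' One independent seeded run per grid point; returns a tidy table of cycle
#' counts, mean period and CV per point.  Sweeping `lambda` across the
#' non-adiabatic/adiabatic range shows stochastic cycling disappearing in
#' the fast-switching limit.
#'
#' @param lambda numeric vector of adiabaticity scalings.
#' @param model `"ATC"` or `"RTC"` (or object/path as in
#'   [run_simulation()]).
#' @param nb binding sites.
#' @param engine simulation engine for each run.
#' @param t_end horizon per run.
#' @param seed base seed; run i uses `seed + i - 1`.
#' @param protocol a [period_protocol()].
#' @return A tibble with one row per grid point: `lambda, n_cycles,
#'   mean_period, cv, seed`.
#' @export
sweep_periods <- function(lambda, model = "ATC", nb = 1L,
                          engine = c("cme", "pdmp", "linear"),
                          t_end = 500, seed = 1L,
                          protocol = period_protocol()) {
  engine <- match.arg(engine)
  purrr::map2_dfr(lambda, seq_along(lambda), function(lam, i) {
    run_seed <- seed + i - 1L
    traj <- run_simulation(model, engine = engine, lambda = lam, nb = nb,
                           t_end = t_end, seed = run_seed, quiet = TRUE)
    ps <- suppressWarnings(detect_periods(traj, protocol))
    g <- glance(ps, n_boot = 0)
    tibble::tibble(lambda = lam, n_cycles = g$n, mean_period = g$mean,
                   cv = g$cv, seed = run_seed)
  })
}

#' Sweep the KB mRNA-lifetime rescale factor
#'
#' One independent seeded KB-model PDMP run per rescale factor `w` (see
#' [rescale_mrna()]): mRNA degradation and translation are scaled together
#' so protein output is fixed while the mRNA lag shrinks with larger `w`.
#' Returns period statistics per grid point.  Requires a user-supplied KB
#' rate set; the period protocol must name an observable column of the KB
#' trajectory (e.g. `"I"`) with explicit thresholds, or use the
#' `"promoter"` method.
#'
#' @param p a [kb_params()] object (config-supplied rates).
#' @param w numeric vector of rescale factors (1 = unchanged).
#' @param t_end horizon per run.
#' @param seed base seed; run i uses `seed + i - 1`.
#' @param protocol a [period_protocol()].
#' @param min_period optional minimum-period filter applied per run.
#' @return A tibble with one row per `w`: `w, n_cycles, mean_period, cv,
#'   seed`.
#' @export
sweep_mrna_rescale <- function(p, w, t_end = 1000, seed = 1L,
                               protocol = period_protocol(method = "promoter"),
                               min_period = 0) {
  stopifnot(inherits(p, "kb_params"))
  purrr::map2_dfr(w, seq_along(w), function(wi, i) {
    run_seed <- seed + i - 1L
    traj <- simulate_kb_pdmp(rescale_mrna(p, wi), t_end = t_end,
                             seed = run_seed)
    ps <- suppressWarnings(detect_periods(traj, protocol))
    if (min_period > 0) ps <- period_filter(ps, min_period)
    g <- glance(ps, n_boot = 0)
    tibble::tibble(w = wi, n_cycles = g$n, mean_period = g$mean,
                   cv = g$cv, seed = run_seed)
  })
}

#' Adiabatic-limit report: Bendixson certificate plus ODE convergence
#'
#' Runs [no_limit_cycle_check()] and integrates the adiabatic mass-action
#' ODEs from random non-negative initial conditions, reporting whether every
#' trajectory settles to a fixed point (trailing-window displacement below
#' `tol`).
#'
#' @param p a [titration_params()] object.
#' @param n_init number of random initial conditions.
#' @param t_end integration horizon.
#' @param tol convergence displacement tolerance over the trailing window.
#' @param seed RNG seed for the initial conditions.
#' @param n_grid Bendixson grid resolution per axis.
#' @return A list: `no_limit_cycle`, `worst_trace`, `all_converged`,
#'   `max_displacement`, `fixed_points` (tibble of final states).
#' @export
check_adiabatic <- function(p, n_init = 20, t_end = 200, tol = 1e-6,
                            seed = 1L, n_grid = 200) {
  bend <- no_limit_cycle_check(p, n_grid = n_grid)
  set.seed(seed)
  beta_max <- max(p$beta_f_X, p$beta_b_X, p$beta_f_Y, p$beta_b_Y)
  finals <- purrr::map_dfr(seq_len(n_init), function(i) {
    init <- runif(2, 0, 2 * beta_max)
    traj <- simulate_adiabatic(p, init = init, t_end = t_end, dt = 0.1)
    tail_win <- traj[traj$time >= t_end - 10, ]
    disp <- max(abs(diff(tail_win$x)), abs(diff(tail_win$y)))
    tibble::tibble(x0 = init[1], y0 = init[2],
                   x_end = tail_win$x[nrow(tail_win)],
                   y_end = tail_win$y[nrow(tail_win)],
                   displacement = disp)
  })
  list(no_limit_cycle = bend$no_limit_cycle,
       worst_trace = bend$worst_trace,
       all_converged = all(finals$displacement < tol),
       max_displacement = max(finals$displacement),
       fixed_points = finals)
}

#' Write a period-sample summary (JSON) and the raw periods (CSV)
#'
#' @param sample a `period_sample`.
#' @param summary_path JSON output path.
#' @param periods_path optional CSV of the raw periods, one per row.
#' @return `summary_path`, invisibly.
#' @export
write_period_summary <- function(sample, summary_path, periods_path = NULL) {
  g <- glance(sample, n_boot = 0)
  proto <- sample$protocol
  jsonlite::write_json(
    list(n = g$n, mean = g$mean, variance = g$variance, cv = g$cv,
         n_discarded = g$n_discarded,
         protocol = if (!is.null(proto)) unclass(proto) else NULL),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(periods_path)) {
    utils::write.csv(tidy(sample), periods_path, row.names = FALSE)
  }
  invisible(summary_path)
}
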