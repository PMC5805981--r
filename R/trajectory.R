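#' Trajectory container
#'
#' All simulation engines return a *trajectory*: a tibble with one row per
#' stored time point, columns `time`, `x`, `y` (concentrations), `s_X`, `s_Y`
#' (promoter occupancies) and `event` (switching-channel label at event rows,
#' `NA` at grid snapshots), plus engine metadata in attributes.  CME
#' trajectories carry additional `N_X`, `N_Y` copy-number columns and are
#' piecewise constant; PDMP-family trajectories are piecewise smooth, sampled
#' on a regular grid with every switching instant included.
#'
#' @param df data frame of states.
#' @param engine engine name string.
#' @param params the [titration_params()] (or extended-model parameter list)
#'   used.
#' @param seed the RNG seed of the run.
#' @param ... further metadata stored as attributes (e.g. `n_events`,
#'   `events`).
#' @return A tibble of class `circuit_trajectory`.
#' @keywords internal
new_trajectory <- function(df, engine, params, seed, ...) {
  out <- tibble::as_tibble(df)
  attr(out, "engine") <- engine
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("circuit_trajectory", class(out))
  out
}

#' Metadata of a trajectory
#'
#' @param traj a trajectory.
#' @return A list with `engine`, `params`, `seed`, `n_events` (when the
#'   engine counts events).
#' @export
trajectory_meta <- function(traj) {
  list(engine = attr(traj, "engine"),
       params = attr(traj, "params"),
       seed = attr(traj, "seed"),
       n_events = attr(traj, "n_events"))
}

#' Time-weighted promoter-state occupancy
#'
#' Fraction of simulated time spent in each promoter state `(s_X, s_Y)`
#' (or in each `s` of a single gene), weighted by the holding time of each
#' stored row.  Fractions sum to 1.
#'
#' @param traj a trajectory (any engine).
#' @param gene optionally `"X"` or `"Y"` to marginalize onto one promoter.
#' @return A tibble with the state columns and `fraction`.
#' @export
occupancy_stats <- function(traj, gene = NULL) {
  if (nrow(traj) < 1L) {
    abort("trajectory is empty.", class = "pdmposc_trajectory_error")
  }
  tt <- traj$time
  wt <- diff(c(tt, tt[length(tt)]))
  if (nrow(traj) == 1L) wt <- 1
  df <- tibble::tibble(s_X = traj$s_X, s_Y = traj$s_Y, wt = wt)
  if (!is.null(gene)) {
    gene <- match.arg(gene, c("X", "Y"))
    df$s <- if (gene == "X") df$s_X else df$s_Y
    out <- df |>
      dplyr::group_by(.data$s) |>
      dplyr::summarise(fraction = sum(.data$wt), .groups = "drop")
  } else {
    out <- df |>
      dplyr::group_by(.data$s_X, .data$s_Y) |>
      dplyr::summarise(fraction = sum(.data$wt), .groups = "drop")
  }
  out$fraction <- out$fraction / sum(out$fraction)
  out
}

#' Plot a trajectory
#'
#' Concentrations of X and Y over time, with the promoter occupancy of the
#' regulated gene as a step trace underneath.
#'
#' @param object a trajectory.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_trajectory <- function(object, ...) {
  p <- attr(object, "params")
  long <- tibble::tibble(
    time = rep(object$time, 2L),
    species = rep(c("x", "y"), each = nrow(object)),
    concentration = c(object$x, object$y)
  )
  gg <- ggplot2::ggplot(long,
                        ggplot2::aes(x = .data$time, y = .data$concentration,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration",
                  title = paste0(attr(object, "engine"), " trajectory"),
                  subtitle = if (!is.null(p$circuit)) p$circuit else NULL) +
    ggplot2::theme_minimal()
  gg
}

#' Write / read a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV has the standard column schema (`time, x, y, N_X, N_Y, s_X, s_Y,
#' event` — copy-number columns only when present); the sidecar records
#' engine, seed and the full parameter set so a stored run can be
#' reconstructed exactly.
#'
#' @param traj a trajectory.
#' @param path CSV file path.
#' @param meta_path JSON sidecar path; default replaces the extension with
#'   `.meta.json`.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a trajectory.
#' @export
write_trajectory <- function(traj, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.csv$", "", path),
                                              ".meta.json")
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- trajectory_meta(traj)
  pl <- meta$params
  if (inherits(pl, "titration_params")) pl <- as_config(pl)
  jsonlite::write_json(
    list(engine = meta$engine, seed = meta$seed, params = pl,
         n_events = meta$n_events),
    meta_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.csv$", "", path),
                                              ".meta.json")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  params <- meta$params
  if (!is.null(params) && !is.null(params$Omega)) {
    params <- params_from_config(params)
  }
  new_trajectory(df, engine = meta$engine %||% "unknown",
                 params = params, seed = meta$seed,
                 n_events = meta$n_events)
}
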