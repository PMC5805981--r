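#' Parameter set for the idealized titration circuits
#'
#' Builds the full rate-constant set for the two-gene titration motifs: a
#' transcription factor X and an inhibitor Y that irreversibly titrates X into
#' an inactive complex.  X binds sequentially to the `nb` sites of the
#' regulated promoter; production of the regulated gene is `beta_f` while the
#' promoter is empty and `beta_b` as soon as one site is occupied.  The
#' adiabaticity scaling `lam` multiplies the TF-promoter association and
#' dissociation rates (and nothing else), so `lam >> 1` is the fast-switching
#' (adiabatic) regime and `lam ~ 1` the non-adiabatic regime.
#'
#' All rates are in units of the protein degradation rate (time is
#' dimensionless); concentrations are molecules per `Omega`.
#'
#' @param Omega system size: molecule copies per unit concentration (>= 1).
#' @param lam adiabaticity scaling factor applied to `kappa_*0` and
#'   `theta_*0` (> 0).
#' @param nb_X,nb_Y number of sequential binding sites on the promoters of
#'   genes X and Y (non-negative integers; 0 means the gene is constitutive).
#' @param beta_f_X,beta_b_X production rate of gene X with the promoter free /
#'   bound (concentration per time).
#' @param beta_f_Y,beta_b_Y production rate of gene Y with the promoter free /
#'   bound.
#' @param delta_X,delta_Y first-order degradation rates of X and Y.
#' @param kappa_X0,kappa_Y0 base association rates of X to the promoters of
#'   genes X and Y; effective rates are `kappa_*0 * lam`.
#' @param theta_X0,theta_Y0 base dissociation rates; effective rates are
#'   `theta_*0 * lam`.
#' @param alpha bimolecular titration (sequestration) rate of X by Y.
#' @param circuit preset tag: "ATC", "RTC" or "custom".
#'
#' @return An object of class `titration_params`: a named list carrying the
#'   base rates plus the effective, `lam`-scaled `kappa_X`, `kappa_Y`,
#'   `theta_X`, `theta_Y`.
#' @seealso [atc_params()], [rtc_params()] for the built-in presets.
#' @export
titration_params <- function(Omega = 1000, lam = 1,
                             nb_X = 0L, nb_Y = 0L,
                             beta_f_X = 0, beta_b_X = 0,
                             beta_f_Y = 0, beta_b_Y = 0,
                             delta_X = 1, delta_Y = 1,
                             kappa_X0 = 0, kappa_Y0 = 0,
                             theta_X0 = 0, theta_Y0 = 0,
                             alpha = 0,
                             circuit = "custom") {
  num_fields <- list(
    Omega = Omega, lam = lam,
    beta_f_X = beta_f_X, beta_b_X = beta_b_X,
    beta_f_Y = beta_f_Y, beta_b_Y = beta_b_Y,
    delta_X = delta_X, delta_Y = delta_Y,
    kappa_X0 = kappa_X0, kappa_Y0 = kappa_Y0,
    theta_X0 = theta_X0, theta_Y0 = theta_Y0,
    alpha = alpha
  )
  for (nm in names(num_fields)) {
    v <- num_fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort(paste0("`", nm, "` must be a single non-negative number."),
            class = "pdmposc_parameter_error")
    }
  }
  if (Omega < 1) {
    abort("`Omega` must be >= 1.", class = "pdmposc_parameter_error")
  }
  if (lam <= 0) {
    abort("`lam` must be > 0.", class = "pdmposc_parameter_error")
  }
  for (nm in c("nb_X", "nb_Y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v)) {
      abort(paste0("`", nm, "` must be a single non-negative integer."),
            class = "pdmposc_parameter_error")
    }
  }
  circuit <- match.arg(circuit, c("custom", "ATC", "RTC"))
  p <- c(num_fields, list(nb_X = as.integer(nb_X), nb_Y = as.integer(nb_Y),
                          circuit = circuit))
  # effective, lam-scaled promoter kinetics
  p$kappa_X <- p$kappa_X0 * lam
  p$kappa_Y <- p$kappa_Y0 * lam
  p$theta_X <- p$theta_X0 * lam
  p$theta_Y <- p$theta_Y0 * lam
  structure(p, class = "titration_params")
}

#' Activator-titration circuit (ATC) preset
#'
#' The idealized ATC: X is a constitutively produced activator that binds the
#' `nb` sites of the inhibitor gene Y promoter and switches Y production from
#' 0 (free) to 10 (bound); Y titrates X at rate `alpha = 10`.  All values are
#' the standard published set for this motif (`Omega = 10^3`, `beta_X = 2`,
#' `delta = 1`, `kappa_Y = lam`, `theta_Y = 0.5 lam`).
#'
#' @param lam adiabaticity scaling factor (> 0); `lam = 1` is the
#'   non-adiabatic regime, `lam = 10^3` the adiabatic regime.
#' @param nb number of binding sites on the promoter of gene Y (>= 1).
#' @return A [titration_params()] object.
#' @examples
#' p <- atc_params(lam = 1, nb = 1)
#' p$kappa_Y   # 1
#' p$theta_Y   # 0.5
#' @export
atc_params <- function(lam = 1, nb = 1L) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam <= 0) {
    abort("`lam` must be a single positive number.",
          class = "pdmposc_parameter_error")
  }
  if (!is.numeric(nb) || length(nb) != 1L || is.na(nb) || nb < 1 ||
      nb != round(nb)) {
    abort("`nb` must be a single integer >= 1.",
          class = "pdmposc_parameter_error")
  }
  titration_params(
    Omega = 1000, lam = lam, nb_X = 0L, nb_Y = as.integer(nb),
    beta_f_X = 2, beta_b_X = 2, beta_f_Y = 0, beta_b_Y = 10,
    delta_X = 1, delta_Y = 1,
    kappa_X0 = 0, kappa_Y0 = 1, theta_X0 = 0, theta_Y0 = 0.5,
    alpha = 10, circuit = "ATC"
  )
}

#' Repressor-titration circuit (RTC) preset
#'
#' The idealized RTC: X represses its own promoter (production 10 free, 0
#' bound) and the inhibitor Y is constitutive at rate 2; Y titrates X at rate
#' `alpha = 10`.  Binding/unbinding of X at its own promoter scale with `lam`
#' (`kappa_X = 0.2 lam`, `theta_X = 0.4 lam`).
#'
#' @inheritParams atc_params
#' @param nb number of binding sites on the promoter of gene X (>= 1).
#' @return A [titration_params()] object.
#' @export
rtc_params <- function(lam = 1, nb = 1L) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam <= 0) {
    abort("`lam` must be a single positive number.",
          class = "pdmposc_parameter_error")
  }
  if (!is.numeric(nb) || length(nb) != 1L || is.na(nb) || nb < 1 ||
      nb != round(nb)) {
    abort("`nb` must be a single integer >= 1.",
          class = "pdmposc_parameter_error")
  }
  titration_params(
    Omega = 1000, lam = lam, nb_X = as.integer(nb), nb_Y = 0L,
    beta_f_X = 10, beta_b_X = 0, beta_f_Y = 2, beta_b_Y = 2,
    delta_X = 1, delta_Y = 1,
    kappa_X0 = 0.2, kappa_Y0 = 0, theta_X0 = 0.4, theta_Y0 = 0,
    alpha = 10, circuit = "RTC"
  )
}

#' @export
print.titration_params <- function(x, ...) {
  cat("<titration_params> circuit:", x$circuit,
      " lambda:", x$lam, " Omega:", x$Omega, "\n")
  cat("  sites: nb_X =", x$nb_X, ", nb_Y =", x$nb_Y, "\n")
  cat("  production: beta_X (f/b) =", x$beta_f_X, "/", x$beta_b_X,
      "; beta_Y (f/b) =", x$beta_f_Y, "/", x$beta_b_Y, "\n")
  cat("  degradation: delta_X =", x$delta_X, ", delta_Y =", x$delta_Y,
      "; titration alpha =", x$alpha, "\n")
  cat("  promoter kinetics (effective): kappa_X =", x$kappa_X,
      ", theta_X =", x$theta_X, "; kappa_Y =", x$kappa_Y,
      ", theta_Y =", x$theta_Y, "\n")
  invisible(x)
}

#' Production rate of a gene given its promoter occupancy
#'
#' Production is `beta_f` when no site is occupied and `beta_b` when any site
#' is occupied, for the promoter of the requested gene.
#'
#' @param s promoter occupancy (number of bound X), `0 <= s <= nb` of that
#'   gene.
#' @param gene `"X"` or `"Y"`.
#' @param p a [titration_params()] object.
#' @return Production rate (concentration per time).
#' @export
production_rate <- function(s, gene = c("X", "Y"), p) {
  gene <- match.arg(gene)
  nb <- if (gene == "X") p$nb_X else p$nb_Y
  if (any(s < 0 | s > nb | s != round(s))) {
    abort(paste0("promoter occupancy `s` must be an integer in [0, ", nb,
                 "] for gene ", gene, "."),
          class = "pdmposc_state_error")
  }
  bf <- if (gene == "X") p$beta_f_X else p$beta_f_Y
  bb <- if (gene == "X") p$beta_b_X else p$beta_b_Y
  ifelse(s == 0, bf, bb)
}

# which gene carries a regulated (nb > 0) promoter; NA if none
regulated_gene <- function(p) {
  if (p$nb_X > 0L) "X" else if (p$nb_Y > 0L) "Y" else NA_character_
}

param_field_names <- c(
  "Omega", "lambda", "nb_X", "nb_Y",
  "beta_f_X", "beta_b_X", "beta_f_Y", "beta_b_Y",
  "delta_X", "delta_Y",
  "kappa_X0", "kappa_Y0", "theta_X0", "theta_Y0", "alpha", "circuit"
)

#' Serialize / deserialize a parameter set to structured text (YAML)
#'
#' Keys follow the standard symbols (`Omega`, `lambda`, `nb_X`, `beta_f_X`,
#' ...).  A config may instead name a built-in `preset` ("ATC" or "RTC") with
#' optional `lambda` / `nb` and per-key overrides.
#'
#' @param p a [titration_params()] object.
#' @param path file path.
#' @return `read_params()` returns a [titration_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "titration_params"))
  out <- list(
    Omega = p$Omega, lambda = p$lam, nb_X = p$nb_X, nb_Y = p$nb_Y,
    beta_f_X = p$beta_f_X, beta_b_X = p$beta_b_X,
    beta_f_Y = p$beta_f_Y, beta_b_Y = p$beta_b_Y,
    delta_X = p$delta_X, delta_Y = p$delta_Y,
    kappa_X0 = p$kappa_X0, kappa_Y0 = p$kappa_Y0,
    theta_X0 = p$theta_X0, theta_Y0 = p$theta_Y0,
    alpha = p$alpha, circuit = p$circuit
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  params_from_config(cfg)
}

#' Build a parameter set from a parsed config list
#'
#' @param cfg a named list, either naming a `preset` ("ATC"/"RTC", with
#'   optional `lambda`, `nb` and per-key overrides) or giving the full key set
#'   used by [write_params()].
#' @return A [titration_params()] object.
#' @export
params_from_config <- function(cfg) {
  if (!is.null(cfg$preset)) {
    preset <- toupper(cfg$preset)
    lam <- cfg$lambda %||% 1
    nb <- cfg$nb %||% 1L
    p <- switch(preset,
      ATC = atc_params(lam = lam, nb = nb),
      RTC = rtc_params(lam = lam, nb = nb),
      abort(paste0("unknown preset: ", cfg$preset),
            class = "pdmposc_parameter_error")
    )
    overrides <- cfg[setdiff(names(cfg), c("preset", "lambda", "nb"))]
    if (length(overrides)) {
      full <- as_config(p)
      full[names(overrides)] <- overrides
      p <- params_from_config(full)
    }
    return(p)
  }
  missing <- setdiff(setdiff(param_field_names, "circuit"), names(cfg))
  if (length(missing)) {
    abort(paste0("config is missing keys: ", paste(missing, collapse = ", ")),
          class = "pdmposc_parameter_error")
  }
  titration_params(
    Omega = cfg$Omega, lam = cfg$lambda,
    nb_X = cfg$nb_X, nb_Y = cfg$nb_Y,
    beta_f_X = cfg$beta_f_X, beta_b_X = cfg$beta_b_X,
    beta_f_Y = cfg$beta_f_Y, beta_b_Y = cfg$beta_b_Y,
    delta_X = cfg$delta_X, delta_Y = cfg$delta_Y,
    kappa_X0 = cfg$kappa_X0, kappa_Y0 = cfg$kappa_Y0,
    theta_X0 = cfg$theta_X0, theta_Y0 = cfg$theta_Y0,
    alpha = cfg$alpha,
    circuit = cfg$circuit %||% "custom"
  )
}

as_config <- function(p) {
  list(
    Omega = p$Omega, lambda = p$lam, nb_X = p$nb_X, nb_Y = p$nb_Y,
    beta_f_X = p$beta_f_X, beta_b_X = p$beta_b_X,
    beta_f_Y = p$beta_f_Y, beta_b_Y = p$beta_b_Y,
    delta_X = p$delta_X, delta_Y = p$delta_Y,
    kappa_X0 = p$kappa_X0, kappa_Y0 = p$kappa_Y0,
    theta_X0 = p$theta_X0, theta_Y0 = p$theta_Y0,
    alpha = p$alpha, circuit = p$circuit
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
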