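# Config-file driven workflow: flat key-value (JSON) configs, schema
# validation, CSV/JSON outputs, bundled fixture parameter sets.

SCHEMA_VERSION <- "llpsagg-summary/1"

config_schema <- function() {
  list(
    model = list(type = "character", default = "quasi_equilibrium",
                 choices = c("finite_exchange", "quasi_equilibrium",
                             "homogeneous")),
    phi_I = list(type = "numeric", default = 1),
    phi_II = list(type = "numeric", default = 0),
    phi_bar = list(type = "numeric", default = 0.01),
    delta_chi = list(type = "numeric", default = 0),
    nu_ratio = list(type = "numeric", default = 1),
    gamma = list(type = "numeric", default = NA_real_), # NA: derive from thermodynamics
    k1 = list(type = "numeric", default = 1e-8),
    n1 = list(type = "numeric", default = 2),
    k2 = list(type = "numeric", default = 1e-4),
    n2 = list(type = "numeric", default = 2),
    k_plus = list(type = "numeric", default = 5e3),
    k_exchange = list(type = "numeric", default = 1e3),
    c_tot = list(type = "numeric", default = 1),
    t_end = list(type = "numeric", default = NA_real_), # NA: 40 / kappa
    rtol = list(type = "numeric", default = 1e-8),
    atol = list(type = "numeric", default = NA_real_),  # NA: 1e-12 * m_tot
    n_out = list(type = "numeric", default = 400),
    plateau_tol = list(type = "numeric", default = 1e-3),
    monomer_tol = list(type = "numeric", default = 1e-6),
    sweep_gamma_min = list(type = "numeric", default = 1.1),
    sweep_gamma_max = list(type = "numeric", default = 30),
    sweep_gamma_n = list(type = "numeric", default = 20),
    sweep_phi_bar_min = list(type = "numeric", default = 0.01),
    sweep_phi_bar_max = list(type = "numeric", default = 0.9),
    sweep_phi_bar_n = list(type = "numeric", default = 20),
    label = list(type = "character", default = "run")
  )
}

#' Default run configuration
#'
#' The flat key-value configuration driving [run_simulation()] and
#' [run_sweep()]. Thermodynamic keys (`phi_I`, `phi_II`, `phi_bar`,
#' `delta_chi`, `nu_ratio`) define the two-phase system; `gamma` may be set
#' directly to override the thermodynamically derived partition coefficient
#' (useful for sweeps where Gamma is the control variable). Kinetic keys map
#' onto [kinetic_rates()]; solver keys onto [solver_options()]; `NA` values
#' mean "derive at run time" (`gamma` from the phase spec, `t_end` as
#' `40 / kappa`, `atol` as `1e-12 * m_tot`).
#'
#' @return A named list with every key set to its default.
#' @export
default_config <- function() {
  lapply(config_schema(), function(s) s$default)
}

#' Validate a run configuration against the schema
#'
#' Checks types and value ranges and rejects unknown keys, so that a typo in
#' a config file fails loudly instead of silently using a default.
#'
#' @param config A named list (e.g. from [read_config()]).
#' @return The validated config, invisibly. Errors name the offending key.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in names(config)) {
    s <- schema[[key]]
    v <- config[[key]]
    if (length(v) != 1L) {
      stop("config key '", key, "' must be a single value", call. = FALSE)
    }
    if (s$type == "numeric" && !is.numeric(v)) {
      stop("config key '", key, "' must be numeric", call. = FALSE)
    }
    if (s$type == "character") {
      if (!is.character(v)) {
        stop("config key '", key, "' must be a string", call. = FALSE)
      }
      if (!is.null(s$choices) && !(v %in% s$choices)) {
        stop("config key '", key, "' must be one of: ",
             paste(s$choices, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' Resolve a partial configuration to a complete one
#'
#' Fills unspecified keys with defaults and derives `gamma` (from the phase
#' specification, unless set explicitly), the compartment volume fraction,
#' the characteristic rate `kappa`, and the integration horizon.
#'
#' @param config A named list of overrides (may be empty).
#' @return The fully resolved config (all keys present, derived values
#'   filled), with derived entries `vI_frac` and `kappa` attached as
#'   attributes.
#' @export
resolve_config <- function(config = list()) {
  validate_config(config)
  full <- default_config()
  full[names(config)] <- config
  spec <- phase_spec(full$phi_I, full$phi_II, full$phi_bar,
                     full$delta_chi, full$nu_ratio)
  if (is.na(full$gamma)) {
    full$gamma <- monomer_partition_coefficient(spec)
  }
  rates <- config_rates(full)
  kappa <- characteristic_rate(rates, full$c_tot)
  if (is.na(full$t_end)) full$t_end <- 40 / kappa
  attr(full, "vI_frac") <- if (full$phi_I > full$phi_II) {
    compartment_volume_fraction(spec)
  } else NA_real_
  attr(full, "kappa") <- kappa
  full
}

config_rates <- function(full) {
  kinetic_rates(k1 = full$k1, n1 = full$n1, k2 = full$k2, n2 = full$n2,
                k_plus = full$k_plus, k_exchange = full$k_exchange)
}

config_solver <- function(full) {
  solver_options(rtol = full$rtol,
                 atol = if (is.na(full$atol)) NULL else full$atol,
                 n_out = full$n_out)
}

#' Read / write configuration files
#'
#' Configs are stored as flat JSON objects, one per run.
#'
#' @param path File path.
#' @param config A named list (validated before writing).
#' @return `read_config` returns the validated named list; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON null marks "derive at run time"; drop so defaults apply
  config <- config[!vapply(config, is.null, logical(1))]
  validate_config(config)
  config
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  # 17 significant digits: numeric round-trip safety for derived values
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

# Full-precision (round-trip safe) CSV writer.
write_precise_csv <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' Writes the fixed column set
#' `time, c_a_I, M_a_I, M_m_I, c_a_II, M_a_II, M_m_II, mass_residual`
#' (two-compartment) or `time, c_a, M_a, M_m, mass_residual` (homogeneous)
#' at full float precision, so reading the file back reproduces the values
#' bit for bit.
#'
#' @param traj An `aggregation_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "aggregation_trajectory"))
  write_precise_csv(as.data.frame(traj), path)
}

#' Run one simulation from a configuration
#'
#' Resolves the config, integrates the selected model, reads out the
#' asymptotic state, and (optionally) writes `trajectory.csv`,
#' `summary.json` and the fully resolved `config.json` to `out_dir`. One
#' structured log line per integration reports duration, mass residual and
#' the plateau certificate.
#'
#' @param config A named list of config overrides, or a path to a JSON
#'   config file.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing files.
#' @param quiet Suppress the log line.
#' @return A list with `trajectory`, `summary`, `config` (resolved), and
#'   `files` (paths written, if any).
#' @export
run_simulation <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  full <- resolve_config(config)
  rates <- config_rates(full)
  solver <- config_solver(full)
  t0 <- proc.time()[["elapsed"]]
  if (full$model == "homogeneous") {
    traj <- simulate_homogeneous(full$c_tot, rates, full$t_end, solver)
  } else {
    spec <- phase_spec(full$phi_I, full$phi_II, full$phi_bar,
                       full$delta_chi, full$nu_ratio)
    init <- initial_state_at_partition_equilibrium(full$c_tot, spec)
    sim_fun <- if (full$model == "quasi_equilibrium") {
      simulate_quasi_equilibrium
    } else {
      simulate_compartments
    }
    traj <- sim_fun(init, rates, full$gamma, full$t_end, solver)
  }
  summ <- asymptotic_readout(traj, plateau_tol = full$plateau_tol,
                             monomer_tol = full$monomer_tol, on_fail = "na")
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!quiet) {
    message(sprintf(
      "[llpsagg] run=%s model=%s gamma=%.4g duration=%.2fs mass_residual=%.2e plateau=%s(%s)",
      full$label, full$model, full$gamma, elapsed,
      max(abs(traj$mass_residual)), summ$converged, summ$criterion))
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    traj_path <- file.path(out_dir, "trajectory.csv")
    write_trajectory_csv(traj, traj_path)
    summary_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary_record(summ, traj), summary_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    config_path <- file.path(out_dir, "config.json")
    write_config(unclass_attrs(full), config_path)
    files <- c(trajectory = traj_path, summary = summary_path,
               config = config_path)
  }
  list(trajectory = traj, summary = summ, config = full, files = files)
}

unclass_attrs <- function(full) {
  attributes(full) <- list(names = names(full))
  full
}

summary_record <- function(summ, traj) {
  rec <- list(schema_version = SCHEMA_VERSION,
              model = summ$model,
              gamma = summ$gamma,
              vI_frac = summ$vI_frac,
              converged = summ$converged,
              criterion = summ$criterion,
              t_readout = summ$t_readout,
              monomer_fraction = summ$monomer_fraction,
              mass_residual_max = max(abs(traj$mass_residual)))
  if (!is.null(summ$c_a_I_inf)) {
    rec$c_a_I_inf <- summ$c_a_I_inf
    rec$c_a_II_inf <- summ$c_a_II_inf
    rec$M_a_I_inf <- summ$M_a_I_inf
    rec$M_a_II_inf <- summ$M_a_II_inf
    if (isTRUE(summ$converged)) {
      rec$epsilon <- summ$c_a_I_inf / summ$c_a_II_inf
    }
  } else {
    rec$c_a_inf <- summ$c_a_inf
    rec$M_a_inf <- summ$M_a_inf
  }
  rec
}

#' Run a parameter sweep from a configuration
#'
#' Delegates to [sweep_partitioning()] using the `sweep_*` grid keys of the
#' config, and (optionally) writes `sweep.csv` (long format:
#' `phi_bar, gamma, vI_frac, epsilon, C, ca_tot, converged`), the extracted
#' sign boundary as `boundary.csv`, and a `metadata.json` header recording
#' the grids, rates and package version.
#'
#' @inheritParams run_simulation
#' @return A list with `sweep` (a `sweep_result`), `boundary`, `config`,
#'   and `files`.
#' @export
run_sweep <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  full <- resolve_config(config)
  rates <- config_rates(full)
  solver <- config_solver(full)
  gamma_grid <- exp(seq(log(full$sweep_gamma_min), log(full$sweep_gamma_max),
                        length.out = full$sweep_gamma_n))
  phi_grid <- seq(full$sweep_phi_bar_min, full$sweep_phi_bar_max,
                  length.out = full$sweep_phi_bar_n)
  t0 <- proc.time()[["elapsed"]]
  sw <- sweep_partitioning(
    rates = rates, gamma = gamma_grid, phi_bar = phi_grid,
    phi_I = full$phi_I, phi_II = full$phi_II, c_tot = full$c_tot,
    model = if (full$model == "finite_exchange") "finite_exchange" else "quasi_equilibrium",
    solver = solver, plateau_tol = full$plateau_tol,
    monomer_tol = full$monomer_tol)
  boundary <- extract_sign_boundary(sw)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!quiet) {
    message(sprintf(
      "[llpsagg] sweep=%s model=%s points=%d converged=%d duration=%.1fs boundary_points=%d",
      full$label, sw$model, nrow(sw$grid), sum(sw$grid$converged), elapsed,
      nrow(boundary)))
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sweep_path <- file.path(out_dir, "sweep.csv")
    write_precise_csv(sw$grid, sweep_path)
    boundary_path <- file.path(out_dir, "boundary.csv")
    write_precise_csv(boundary, boundary_path)
    meta_path <- file.path(out_dir, "metadata.json")
    jsonlite::write_json(
      list(schema_version = SCHEMA_VERSION,
           package_version = as.character(utils::packageVersion("llpsagg")),
           model = sw$model, ca_hom = sw$ca_hom,
           gamma_grid = sw$gamma, phi_bar_grid = sw$phi_bar,
           rates = unclass(sw$rates)[c("k1", "n1", "k2", "n2", "k_plus",
                                       "k_exchange")]),
      meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    config_path <- file.path(out_dir, "config.json")
    write_config(unclass_attrs(full), config_path)
    files <- c(sweep = sweep_path, boundary = boundary_path,
               metadata = meta_path, config = config_path)
  }
  list(sweep = sw, boundary = boundary, config = full, files = files)
}

#' Bundled fixture parameter sets
#'
#' Named configurations mirroring the canonical scenarios of the model:
#' `fig3` (weak-partitioning two-compartment run, Gamma = 3 with
#' `n1 = n2 = 2` and a small compartment), `fig3e_primary` and
#' `fig3e_secondary` (volume-sensitivity sweeps for `n2 = 0` and `n2 = 2`),
#' `fig5a` (fragmentation-like sweep, `n2 = 0`), `fig5bc`
#' (strong secondary nucleation, `n2 = 3`), and `boundary`
#' (the volume-independent case `n2 = n1 - 1`).
#'
#' @param dir Optional directory; if given, each fixture is written to
#'   `<dir>/<name>.json`.
#' @return A named list of config lists (invisibly when `dir` is given).
#' @export
make_fixtures <- function(dir = NULL) {
  gamma3 <- list(phi_I = 1, phi_II = 0, delta_chi = log(3)) # Gamma = 3
  fixtures <- list(
    fig3 = c(gamma3, list(phi_bar = 0.01, n1 = 2, n2 = 2,
                          model = "quasi_equilibrium", label = "fig3")),
    fig3e_primary = c(gamma3, list(n1 = 2, n2 = 0, model = "quasi_equilibrium",
                                   sweep_gamma_min = 3, sweep_gamma_max = 3,
                                   sweep_gamma_n = 1, label = "fig3e_primary")),
    fig3e_secondary = c(gamma3, list(n1 = 2, n2 = 2,
                                     model = "quasi_equilibrium",
                                     sweep_gamma_min = 3, sweep_gamma_max = 3,
                                     sweep_gamma_n = 1,
                                     label = "fig3e_secondary")),
    fig5a = c(gamma3, list(n1 = 2, n2 = 0, model = "quasi_equilibrium",
                           label = "fig5a")),
    fig5bc = c(gamma3, list(n1 = 2, n2 = 3, model = "quasi_equilibrium",
                            label = "fig5bc")),
    boundary = c(gamma3, list(n1 = 2, n2 = 1, model = "quasi_equilibrium",
                              label = "boundary"))
  )
  for (nm in names(fixtures)) validate_config(fixtures[[nm]])
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(fixtures)) {
      write_config(fixtures[[nm]], file.path(dir, paste0(nm, ".json")))
    }
    return(invisible(fixtures))
  }
  fixtures
}
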