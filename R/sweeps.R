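#' Volume-weighted total asymptotic aggregate concentration
#'
#' Combines the per-phase long-time aggregate concentrations into the total
#' per system volume: `ca_tot = (c_a^I(inf) V_I + c_a^II(inf) V_II) / V`.
#'
#' @param summary An `asymptotic_summary` from a converged two-compartment
#'   run (see [asymptotic_readout()]).
#' @param vI_frac Optional compartment volume fraction; defaults to the one
#'   stored in the summary.
#' @return The scalar `ca_tot`.
#' @export
total_asymptotic_concentration <- function(summary, vI_frac = NULL) {
  stopifnot(inherits(summary, "asymptotic_summary"))
  if (!isTRUE(summary$converged)) {
    stop("not converged: refusing to compute a total from a transient readout",
         call. = FALSE)
  }
  if (is.null(vI_frac)) vI_frac <- summary$vI_frac
  stopifnot(vI_frac >= 0, vI_frac <= 1)
  vI_frac * summary$c_a_I_inf + (1 - vI_frac) * summary$c_a_II_inf
}

#' Relative asymptotic aggregate concentration
#'
#' The fractional change of the total long-time aggregate number relative to
#' the homogeneous system: `C = (ca_tot - ca_hom) / ca_hom`. Positive values
#' mean the compartment increased the total aggregate pool (more, hence
#' shorter, aggregates at fixed total mass); negative values mean fewer but
#' larger aggregates.
#'
#' @param ca_tot Total asymptotic aggregate concentration with compartments.
#' @param ca_hom Asymptotic aggregate concentration of the homogeneous
#'   reference (> 0).
#' @return The scalar (or vector) `C`.
#' @export
relative_asymptotic_concentration <- function(ca_tot, ca_hom) {
  if (any(ca_hom <= 0)) {
    stop("relative asymptotic concentration undefined: ca_hom must be > 0",
         call. = FALSE)
  }
  (ca_tot - ca_hom) / ca_hom
}

# Homogeneous reference run, extended until the plateau certificate holds.
homogeneous_to_plateau <- function(c_tot, rates, t_end,
                                   solver = solver_options(),
                                   max_doublings = 6, plateau_tol = 1e-3,
                                   monomer_tol = 1e-6) {
  for (i in seq_len(max_doublings + 1)) {
    traj <- simulate_homogeneous(c_tot, rates, t_end, solver)
    summ <- asymptotic_readout(traj, plateau_tol = plateau_tol,
                               monomer_tol = monomer_tol, on_fail = "na")
    if (summ$converged) return(summ)
    t_end <- 2 * t_end
  }
  asymptotic_readout(traj, plateau_tol = plateau_tol,
                     monomer_tol = monomer_tol, on_fail = "error")
}

#' Sweep compartment volume and monomer partitioning
#'
#' Runs the aggregation kinetics over a grid of mean volume fractions
#' `phi_bar` (setting the compartment volume through the lever rule) and
#' monomer partition coefficients `Gamma`, and collects for each grid point
#' the aggregate partitioning ratio `epsilon = c_a^I(inf)/c_a^II(inf)`, the
#' total asymptotic aggregate concentration `ca_tot`, and the relative
#' asymptotic aggregate concentration `C` against the matched homogeneous
#' reference. Sweeps default to the fast-exchange (quasi-equilibrium) model;
#' results are deterministic and independent of grid-evaluation order.
#'
#' @param rates A [kinetic_rates()].
#' @param gamma Vector of monomer partition coefficients (default 20
#'   log-spaced points in `[1.1, 30]`, covering weak to strong partitioning).
#' @param phi_bar Vector of mean volume fractions (default 20 linear points
#'   mapping to `V_I/V` in `[0.01, 0.9]` for the default `phi_I`, `phi_II`).
#' @param phi_I,phi_II Coexisting compositions of the two phases
#'   (defaults 1 and 0, so `phi_bar` equals `V_I/V`).
#' @param c_tot Initial total monomer concentration (default 1).
#' @param model `"quasi_equilibrium"` (default) or `"finite_exchange"`.
#' @param t_end Integration horizon; `NULL` (default) uses `40 / kappa` with
#'   `kappa` the characteristic proliferation rate, extended automatically
#'   until the plateau certificate holds.
#' @param solver A [solver_options()].
#' @param plateau_tol,monomer_tol Convergence certificate tolerances, see
#'   [asymptotic_readout()].
#' @return An object of class `sweep_result`: a list with `grid` (a long
#'   data frame with columns `phi_bar, gamma, vI_frac, epsilon, C, ca_tot,
#'   ca_I_inf, ca_II_inf, converged`), `ca_hom` (per-`gamma`-independent
#'   homogeneous reference), `rates`, and the axes.
#' @export
sweep_partitioning <- function(rates = kinetic_rates(),
                               gamma = default_gamma_grid(),
                               phi_bar = default_phi_bar_grid(),
                               phi_I = 1, phi_II = 0,
                               c_tot = 1,
                               model = c("quasi_equilibrium",
                                         "finite_exchange"),
                               t_end = NULL,
                               solver = solver_options(),
                               plateau_tol = 1e-3, monomer_tol = 1e-6) {
  model <- match.arg(model)
  validate_kinetic_rates(rates)
  stopifnot(all(gamma > 0), all(phi_bar >= phi_II), all(phi_bar <= phi_I),
            phi_I > phi_II, c_tot > 0)
  m_tot <- c_tot
  kappa <- characteristic_rate(rates, m_tot)
  if (is.null(t_end)) t_end <- 40 / kappa
  sim_fun <- if (model == "quasi_equilibrium") {
    simulate_quasi_equilibrium
  } else {
    simulate_compartments
  }
  hom <- homogeneous_to_plateau(c_tot, rates, t_end, solver,
                                plateau_tol = plateau_tol,
                                monomer_tol = monomer_tol)
  pts <- expand.grid(phi_bar = phi_bar, gamma = gamma,
                     KEEP.OUT.ATTRS = FALSE)
  n <- nrow(pts)
  res <- data.frame(phi_bar = pts$phi_bar, gamma = pts$gamma,
                    vI_frac = NA_real_, epsilon = NA_real_, C = NA_real_,
                    ca_tot = NA_real_, ca_I_inf = NA_real_,
                    ca_II_inf = NA_real_, converged = FALSE)
  for (i in seq_len(n)) {
    sp <- phase_spec(phi_I, phi_II, pts$phi_bar[i])
    vI <- compartment_volume_fraction(sp)
    res$vI_frac[i] <- vI
    init <- initial_state_at_partition_equilibrium(c_tot, sp)
    summ <- tryCatch(
      run_to_plateau(sim_fun, init, rates, pts$gamma[i], t_end, solver,
                     plateau_tol = plateau_tol,
                     monomer_tol = monomer_tol)$summary,
      error = function(e) NULL
    )
    if (is.null(summ) || !summ$converged) next
    res$converged[i] <- TRUE
    res$ca_I_inf[i] <- summ$c_a_I_inf
    res$ca_II_inf[i] <- summ$c_a_II_inf
    res$epsilon[i] <- summ$c_a_I_inf / summ$c_a_II_inf
    res$ca_tot[i] <- total_asymptotic_concentration(summ)
    res$C[i] <- relative_asymptotic_concentration(res$ca_tot[i],
                                                  hom$c_a_inf)
  }
  structure(list(grid = res, ca_hom = hom$c_a_inf, rates = rates,
                 gamma = sort(unique(gamma)),
                 phi_bar = sort(unique(phi_bar)),
                 phi_I = phi_I, phi_II = phi_II, c_tot = c_tot,
                 model = model),
            class = "sweep_result")
}

#' @rdname sweep_partitioning
#' @export
default_gamma_grid <- function() {
  exp(seq(log(1.1), log(30), length.out = 20))
}

#' @rdname sweep_partitioning
#' @export
default_phi_bar_grid <- function() {
  seq(0.01, 0.9, length.out = 20)
}

#' @export
print.sweep_result <- function(x, ...) {
  g <- x$grid
  cat(sprintf("Parameter sweep (%s model): %d points (%d gamma x %d phi_bar)\n",
              x$model, nrow(g), length(x$gamma), length(x$phi_bar)))
  cat(sprintf("  converged: %d/%d; C range [%.3g, %.3g]; epsilon range [%.3g, %.3g]\n",
              sum(g$converged), nrow(g),
              min(g$C, na.rm = TRUE), max(g$C, na.rm = TRUE),
              min(g$epsilon, na.rm = TRUE), max(g$epsilon, na.rm = TRUE)))
  invisible(x)
}

#' Zero-level boundary of the relative aggregate concentration
#'
#' Extracts the curve in the `(phi_bar, Gamma)` plane on which the relative
#' asymptotic aggregate concentration `C` changes sign, separating the
#' regime of fewer-but-larger aggregates (`C < 0`) from
#' more-but-shorter aggregates (`C > 0`). Zero crossings are located by
#' linear interpolation along the Gamma axis for each `phi_bar`. An empty
#' result is valid and means `C` has a single sign on the grid.
#'
#' @param sweep A `sweep_result` from [sweep_partitioning()], or a list with
#'   components `grid` (long data frame with `phi_bar`, `gamma`, `C`).
#' @return A data frame with columns `phi_bar`, `gamma` of boundary points
#'   (zero rows if no sign change).
#' @export
extract_sign_boundary <- function(sweep) {
  g <- if (inherits(sweep, "sweep_result")) sweep$grid else sweep$grid
  stopifnot(all(c("phi_bar", "gamma", "C") %in% names(g)))
  out <- list()
  for (pb in sort(unique(g$phi_bar))) {
    sl <- g[g$phi_bar == pb & !is.na(g$C), , drop = FALSE]
    sl <- sl[order(sl$gamma), , drop = FALSE]
    if (nrow(sl) < 2) next
    s <- sign(sl$C)
    ix <- which(s[-1] * s[-length(s)] < 0)
    for (i in ix) {
      g1 <- sl$gamma[i]; g2 <- sl$gamma[i + 1]
      c1 <- sl$C[i]; c2 <- sl$C[i + 1]
      out[[length(out) + 1]] <- data.frame(
        phi_bar = pb, gamma = g1 + (g2 - g1) * (0 - c1) / (c2 - c1))
    }
    # exact zeros on grid points count as boundary points too
    for (i in which(s == 0)) {
      out[[length(out) + 1]] <- data.frame(phi_bar = pb, gamma = sl$gamma[i])
    }
  }
  if (length(out) == 0) {
    return(data.frame(phi_bar = numeric(0), gamma = numeric(0)))
  }
  do.call(rbind, out)
}

#' Classify aggregating systems by their optimal compartment size
#'
#' Applies [regime_classify()] to a table of experimentally characterized
#' aggregating systems. A template table listing well-studied systems (Tau,
#' the yeast prion Ure2p, IAPP, Amyloid-beta 40 and 42) with their dominant
#' secondary mechanism is bundled (see [literature_systems_template()]); the
#' numeric reaction orders are experimental inputs the user must fill in.
#'
#' @param systems A data frame with columns `name`, `mechanism`, `n1`, `n2`.
#' @return The input with an added `regime` column.
#' @export
classify_literature_systems <- function(systems) {
  req <- c("name", "mechanism", "n1", "n2")
  if (!is.data.frame(systems) || !all(req %in% names(systems))) {
    stop("systems must be a data frame with columns name, mechanism, n1, n2",
         call. = FALSE)
  }
  missing <- !is.finite(suppressWarnings(as.numeric(systems$n1))) |
    !is.finite(suppressWarnings(as.numeric(systems$n2)))
  if (any(missing)) {
    stop("incomplete reaction orders for system(s): ",
         paste(systems$name[missing], collapse = ", "),
         "; fill in measured n1 and n2 before classifying", call. = FALSE)
  }
  systems$regime <- regime_classify(as.numeric(systems$n1),
                                    as.numeric(systems$n2))
  systems
}

#' @rdname classify_literature_systems
#' @export
literature_systems_template <- function() {
  path <- system.file("extdata", "literature_systems.csv",
                      package = "llpsagg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(name = "character",
                                 mechanism = "character",
                                 n1 = "numeric", n2 = "numeric"))
}
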