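#' Aggregation rate constants and reaction orders
#'
#' Collects the kinetic parameters of nucleation--elongation aggregation:
#' primary nucleation (rate `k1 * M_m^n1`), secondary nucleation
#' (rate `k2 * M_m^n2 * M_a`, with `n2 = 0` describing fibril fragmentation,
#' whose rate is monomer independent) and elongation at fibril ends
#' (rate `2 * k_plus * M_m * c_a`), plus the rate `k_exchange` at which the
#' inter-phase monomer ratio relaxes back to its equilibrium value Gamma.
#'
#' Concentrations are carried as mass concentrations in monomer-mass units
#' throughout (the monomer mass may be set to 1 without loss of generality),
#' so `k1` has units of 1/(time * mass-conc^(n1-1)), `k2` of
#' 1/(time * mass-conc^n2), and `k_plus` of 1/(time * mass-conc).
#'
#' The defaults describe a fibril-forming system in natural units
#' (`m_tot = 1`): elongation is fast compared to nucleation
#' (`k_plus >> k2 >> k1`), so aggregates grow long
#' (mean plateau size `~ sqrt(k_plus/k2) ~ 7000` monomers) and new fibrils
#' are rare events, the generic situation for self-replicating amyloids.
#' The scales are chosen so the secondary proliferation rate
#' `kappa = sqrt(2 k_plus k2 m_tot^(n2+1))` equals 1 (time is measured in
#' `1/kappa`) and the primary-nucleation growth rate
#' `lambda = sqrt(2 k_plus k1 m_tot^n1)` is `1e-2 kappa`, the canonical
#' separation between primary and secondary pathways in
#' secondary-nucleation-dominated amyloid systems.
#'
#' @param k1 Primary-nucleation rate constant (>= 0).
#' @param n1 Primary reaction order (>= 0); the exponent of the monomer
#'   dependence of primary nucleation, not necessarily a nucleus size.
#' @param k2 Secondary-nucleation rate constant (>= 0).
#' @param n2 Secondary reaction order (>= 0); 0 means fragmentation.
#' @param k_plus Elongation rate constant (> 0 for any growth).
#' @param k_exchange Relaxation rate of monomer partitioning towards
#'   equilibrium (>= 0); only used by the finite-exchange model.
#' @param phase_multipliers Optional per-phase factors scaling
#'   `(k1, k2, k_plus)` in phase I and phase II, as a list with components
#'   `I` and `II`, each a named numeric vector with entries `k1`, `k2`,
#'   `k_plus`. Default: all 1 (both phases share the same reaction rates).
#'
#' @return An object of class `kinetic_rates`.
#' @examples
#' kinetic_rates() # secondary-nucleation dominated defaults, kappa = 1
#' kinetic_rates(n2 = 0) # fragmentation
#' @export
kinetic_rates <- function(k1 = 1e-8, n1 = 2, k2 = 1e-4, n2 = 2, k_plus = 5e3,
                          k_exchange = 1e3,
                          phase_multipliers = NULL) {
  if (is.null(phase_multipliers)) {
    phase_multipliers <- list(I = c(k1 = 1, k2 = 1, k_plus = 1),
                              II = c(k1 = 1, k2 = 1, k_plus = 1))
  }
  rates <- structure(
    list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, k_plus = k_plus,
         k_exchange = k_exchange, phase_multipliers = phase_multipliers),
    class = "kinetic_rates"
  )
  validate_kinetic_rates(rates)
  rates
}

validate_kinetic_rates <- function(rates) {
  for (f in c("k1", "n1", "k2", "n2", "k_plus", "k_exchange")) {
    v <- rates[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("kinetic_rates field '%s' must be a single finite number >= 0", f),
           call. = FALSE)
    }
  }
  pm <- rates$phase_multipliers
  if (!is.list(pm) || !all(c("I", "II") %in% names(pm))) {
    stop("phase_multipliers must be a list with components 'I' and 'II'",
         call. = FALSE)
  }
  for (ph in c("I", "II")) {
    v <- pm[[ph]]
    if (!is.numeric(v) || !all(c("k1", "k2", "k_plus") %in% names(v)) ||
        any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("phase_multipliers$%s must be a named non-negative vector with entries k1, k2, k_plus", ph),
           call. = FALSE)
    }
  }
  invisible(rates)
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat("Aggregation rate constants\n")
  cat(sprintf("  primary:    k1 = %g, n1 = %g\n", x$k1, x$n1))
  cat(sprintf("  secondary:  k2 = %g, n2 = %g%s\n", x$k2, x$n2,
              if (x$n2 == 0) " (fragmentation)" else ""))
  cat(sprintf("  elongation: k_plus = %g\n", x$k_plus))
  cat(sprintf("  exchange:   k_exchange = %g\n", x$k_exchange))
  invisible(x)
}

#' Per-compartment aggregation state
#'
#' The moment-closure state of one phase: aggregate number concentration
#' `c_a`, aggregate mass concentration `M_a`, and monomer mass concentration
#' `M_m` (all per unit volume of that phase; mass in monomer-mass units).
#'
#' @param c_a Aggregate number concentration (>= 0).
#' @param M_a Aggregate mass concentration (>= 0).
#' @param M_m Monomer mass concentration (>= 0).
#' @return An object of class `compartment_state`.
#' @export
compartment_state <- function(c_a = 0, M_a = 0, M_m = 0) {
  st <- structure(list(c_a = c_a, M_a = M_a, M_m = M_m),
                  class = "compartment_state")
  validate_compartment_state(st)
  st
}

validate_compartment_state <- function(st) {
  for (f in c("c_a", "M_a", "M_m")) {
    v <- st[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("compartment_state field '%s' must be a single finite number >= 0", f),
           call. = FALSE)
    }
  }
  invisible(st)
}

#' Two-compartment system state
#'
#' @param phase_I,phase_II [compartment_state()] objects for the condensed
#'   and dilute phases.
#' @param vI_frac Compartment volume fraction `V_I/V`, strictly inside
#'   `(0, 1)` for two-compartment dynamics.
#' @return An object of class `system_state`.
#' @export
system_state <- function(phase_I, phase_II, vI_frac) {
  st <- structure(list(phase_I = phase_I, phase_II = phase_II,
                       vI_frac = vI_frac),
                  class = "system_state")
  validate_system_state(st)
  st
}

validate_system_state <- function(st) {
  validate_compartment_state(st$phase_I)
  validate_compartment_state(st$phase_II)
  v <- st$vI_frac
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1) {
    stop("system_state field 'vI_frac' must lie strictly in (0, 1); ",
         "for vI_frac of 0 or 1 use simulate_homogeneous", call. = FALSE)
  }
  invisible(st)
}

#' Volume-weighted total mass density of a system state
#'
#' `m_tot = vI*(M_m^I + M_a^I) + (1 - vI)*(M_m^II + M_a^II)`; this quantity is
#' conserved by the kinetics (monomers are only converted into aggregate mass
#' or exchanged between phases).
#'
#' @param state A [system_state()].
#' @return The scalar total mass density.
#' @export
total_mass_density <- function(state) {
  validate_system_state(state)
  v <- state$vI_frac
  v * (state$phase_I$M_m + state$phase_I$M_a) +
    (1 - v) * (state$phase_II$M_m + state$phase_II$M_a)
}

#' Initial state with monomers at partitioning equilibrium
#'
#' Builds the natural initial condition of the two-compartment kinetics:
#' no aggregates, and the monomer pool split between the phases at the
#' partitioning equilibrium set by the phase specification (monomers
#' equilibrate across the interface on a diffusive time scale that is fast
#' compared to aggregation).
#'
#' @param c_tot Total monomer concentration (per total system volume).
#' @param spec A [phase_spec()] with a strictly interior compartment volume.
#' @param mm Monomer mass (default 1, i.e. concentrations are already mass
#'   concentrations).
#' @return A [system_state()].
#' @export
initial_state_at_partition_equilibrium <- function(c_tot, spec, mm = 1) {
  gamma <- monomer_partition_coefficient(spec)
  vI <- compartment_volume_fraction(spec)
  if (vI <= 0 || vI >= 1) {
    stop("compartment volume fraction is ", vI,
         "; the system is effectively single-phase, use simulate_homogeneous",
         call. = FALSE)
  }
  xi <- partition_degree(gamma, vI)
  cm <- split_monomer_pool(c_tot, gamma, xi)
  system_state(
    phase_I = compartment_state(M_m = cm[["c_m_I"]] * mm),
    phase_II = compartment_state(M_m = cm[["c_m_II"]] * mm),
    vI_frac = vI
  )
}

#' Characteristic rates and nondimensionalization
#'
#' The proliferation rate through secondary pathways is
#' `kappa = sqrt(2 k_plus k2 m_tot^(n2+1))`; in its absence (`k2 = 0`) the
#' natural scale is the primary-nucleation growth rate
#' `lambda = sqrt(2 k_plus k1 m_tot^n1)`. `nondimensionalize` rescales a rate
#' set to units in which `m_tot = 1` and time is measured in `1/kappa`
#' (or `1/lambda` when `k2 = 0`); the returned `time_scale` converts
#' dimensionless times back to the original units.
#'
#' @param rates A [kinetic_rates()].
#' @param m_tot Total mass density (> 0) setting the concentration scale.
#' @return For `characteristic_rate`: the scalar `kappa` (or `lambda`
#'   fallback). For `nondimensionalize`: a list with components `rates`
#'   (rescaled [kinetic_rates()]), `time_scale` (seconds of original time per
#'   dimensionless time unit), `conc_scale` (= `m_tot`).
#' @export
characteristic_rate <- function(rates, m_tot) {
  validate_kinetic_rates(rates)
  stopifnot(m_tot > 0)
  if (rates$k2 > 0 && rates$k_plus > 0) {
    sqrt(2 * rates$k_plus * rates$k2 * m_tot^(rates$n2 + 1))
  } else if (rates$k1 > 0 && rates$k_plus > 0) {
    sqrt(2 * rates$k_plus * rates$k1 * m_tot^rates$n1)
  } else {
    stop("no characteristic rate: need k_plus > 0 and at least one of k1, k2 > 0",
         call. = FALSE)
  }
}

#' @rdname characteristic_rate
#' @export
nondimensionalize <- function(rates, m_tot) {
  kappa <- characteristic_rate(rates, m_tot)
  # k1 ~ 1/(t conc^(n1-1)), k2 ~ 1/(t conc^n2), k_plus ~ 1/(t conc)
  scaled <- kinetic_rates(
    k1 = rates$k1 * m_tot^(rates$n1 - 1) / kappa,
    n1 = rates$n1,
    k2 = rates$k2 * m_tot^rates$n2 / kappa,
    n2 = rates$n2,
    k_plus = rates$k_plus * m_tot / kappa,
    k_exchange = rates$k_exchange / kappa,
    phase_multipliers = rates$phase_multipliers
  )
  list(rates = scaled, time_scale = 1 / kappa, conc_scale = m_tot)
}

#' Undo a nondimensionalization
#'
#' Rescales a dimensionless rate set back to the original units; the
#' round-trip `redimensionalize(nondimensionalize(r, m), m)` is the identity
#' to machine precision.
#'
#' @param nd A list as returned by [nondimensionalize()].
#' @param m_tot The original total mass density.
#' @return A [kinetic_rates()] in the original units.
#' @export
redimensionalize <- function(nd, m_tot) {
  kappa <- 1 / nd$time_scale
  r <- nd$rates
  kinetic_rates(
    k1 = r$k1 * kappa / m_tot^(r$n1 - 1),
    n1 = r$n1,
    k2 = r$k2 * kappa / m_tot^r$n2,
    n2 = r$n2,
    k_plus = r$k_plus * kappa / m_tot,
    k_exchange = r$k_exchange * kappa,
    phase_multipliers = r$phase_multipliers
  )
}
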