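#' Thermodynamic specification of a two-phase system
#'
#' Describes the equilibrium state of a system that has demixed into a
#' condensed compartment (phase I, rich in the compartment-forming component
#' A) and a dilute phase II. Monomers prone to aggregation are assumed dilute,
#' so they partition between the phases without perturbing the coexisting
#' compositions, which are therefore taken as direct inputs; no binodal is
#' solved and finite-size (Laplace-pressure) shifts of the coexisting volume
#' fractions are not applied.
#'
#' @param phi_I Volume fraction of A in the condensed phase I (in `[0, 1]`).
#' @param phi_II Volume fraction of A in the dilute phase II.
#' @param phi_bar Mean volume fraction of A in the whole system; together with
#'   `phi_I` and `phi_II` it fixes the compartment volume through the lever
#'   rule (see [compartment_volume_fraction()]).
#' @param delta_chi Relative interaction strength between the monomers and the
#'   A versus B components, in units of `kB*T`. Positive values favour
#'   partitioning into phase I.
#' @param nu_ratio Molecular-volume ratio of monomer to solvent molecules
#'   (dimensionless, > 0).
#' @param total_volume Total system volume V (arbitrary units, > 0). Only
#'   ratios of volumes enter the theory; the default of 1 is the natural unit.
#'
#' @return An object of class `phase_spec` (a validated list of the fields).
#' @examples
#' sp <- phase_spec(phi_I = 1, phi_II = 0, phi_bar = 0.5, delta_chi = log(3))
#' monomer_partition_coefficient(sp) # 3
#' compartment_volume_fraction(sp)   # 0.5
#' @export
phase_spec <- function(phi_I, phi_II, phi_bar,
                       delta_chi = 0, nu_ratio = 1, total_volume = 1) {
  spec <- structure(
    list(phi_I = phi_I, phi_II = phi_II, phi_bar = phi_bar,
         delta_chi = delta_chi, nu_ratio = nu_ratio,
         total_volume = total_volume),
    class = "phase_spec"
  )
  validate_phase_spec(spec)
  spec
}

validate_phase_spec <- function(spec) {
  for (f in c("phi_I", "phi_II", "phi_bar", "delta_chi", "nu_ratio",
              "total_volume")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("phase_spec field '%s' must be a single finite number", f),
           call. = FALSE)
    }
  }
  if (spec$phi_II < 0 || spec$phi_II > 1) {
    stop("phase_spec field 'phi_II' must lie in [0, 1]", call. = FALSE)
  }
  if (spec$phi_I < 0 || spec$phi_I > 1) {
    stop("phase_spec field 'phi_I' must lie in [0, 1]", call. = FALSE)
  }
  if (spec$phi_I < spec$phi_II) {
    stop("phase_spec field 'phi_I' must be >= 'phi_II' (phase I is the condensed phase)",
         call. = FALSE)
  }
  if (spec$phi_bar < spec$phi_II || spec$phi_bar > spec$phi_I) {
    stop("phase_spec field 'phi_bar' must lie between 'phi_II' and 'phi_I' (lever rule)",
         call. = FALSE)
  }
  if (spec$nu_ratio <= 0) {
    stop("phase_spec field 'nu_ratio' must be > 0", call. = FALSE)
  }
  if (spec$total_volume <= 0) {
    stop("phase_spec field 'total_volume' must be > 0", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.phase_spec <- function(x, ...) {
  cat("Two-phase system specification\n")
  cat(sprintf("  phi_I = %g, phi_II = %g, phi_bar = %g\n",
              x$phi_I, x$phi_II, x$phi_bar))
  cat(sprintf("  delta_chi = %g kB T, nu_ratio = %g, V = %g\n",
              x$delta_chi, x$nu_ratio, x$total_volume))
  gamma <- monomer_partition_coefficient(x)
  cat(sprintf("  monomer partition coefficient Gamma = %g\n", gamma))
  if (x$phi_I > x$phi_II) {
    cat(sprintf("  compartment volume fraction V_I/V = %g\n",
                compartment_volume_fraction(x)))
  }
  invisible(x)
}

#' Equilibrium monomer partition coefficient
#'
#' The ratio `Gamma = c_m^I / c_m^II` of monomer concentrations between the
#' condensed phase I and the dilute phase II at partitioning equilibrium,
#' obtained from the balance of monomer chemical potentials in the two
#' phases:
#' \deqn{\Gamma = \exp[(\nu_m/\nu)\,\Delta\chi\,(\phi_I - \phi_{II})].}
#' Gamma grows exponentially in both the relative interaction strength and
#' the degree of phase separation `phi_I - phi_II`, so weak interactions of a
#' few `kB*T` already give substantial partitioning; it equals 1 at the
#' critical point, where the degree of phase separation vanishes.
#'
#' @param spec A [phase_spec()].
#' @return The positive scalar Gamma.
#' @export
monomer_partition_coefficient <- function(spec) {
  validate_phase_spec(spec)
  exp(spec$nu_ratio * spec$delta_chi * (spec$phi_I - spec$phi_II))
}

#' Compartment volume fraction from the lever rule
#'
#' The fraction of the system volume occupied by the condensed phase I,
#' `V_I/V = (phi_bar - phi_II) / (phi_I - phi_II)`. Increasing the mean
#' amount of compartment material `phi_bar` grows the compartment from
#' `V_I/V = 0` (at `phi_bar = phi_II`) to `V_I/V = 1` (at `phi_bar = phi_I`).
#'
#' @param spec A [phase_spec()] with `phi_I > phi_II`.
#' @return `V_I/V` in `[0, 1]`.
#' @export
compartment_volume_fraction <- function(spec) {
  validate_phase_spec(spec)
  if (spec$phi_I == spec$phi_II) {
    stop("degenerate system: phi_I == phi_II has no two-phase volume; ",
         "use the homogeneous reference model (simulate_homogeneous)",
         call. = FALSE)
  }
  (spec$phi_bar - spec$phi_II) / (spec$phi_I - spec$phi_II)
}

#' Partition degree of the monomer pool
#'
#' The factor `xi = 1 / (1 + (Gamma - 1) V_I/V)` relating the total monomer
#' concentration to the dilute-phase concentration: `c_m^II = xi * c_tot` and
#' `c_m^I = xi * Gamma * c_tot`. For `Gamma > 1`, `xi` decreases from 1 for a
#' vanishingly small compartment to `1/Gamma` when the compartment fills the
#' system, so small compartments achieve the highest monomer mass enrichment.
#'
#' @param gamma Monomer partition coefficient Gamma (> 0).
#' @param vI_frac Compartment volume fraction `V_I/V` in `[0, 1]`.
#' @return The partition degree xi, in `[min(1, 1/Gamma), max(1, 1/Gamma)]`.
#' @export
partition_degree <- function(gamma, vI_frac) {
  stopifnot(is.numeric(gamma), all(gamma > 0),
            is.numeric(vI_frac), all(vI_frac >= 0), all(vI_frac <= 1))
  1 / (1 + (gamma - 1) * vI_frac)
}

#' Split a total monomer pool between the two phases
#'
#' Given the total monomer concentration `c_tot` (per total system volume),
#' returns the per-phase concentrations at partitioning equilibrium,
#' `c_m^I = xi * Gamma * c_tot` and `c_m^II = xi * c_tot`. With `xi` produced
#' by [partition_degree()] the volume-weighted mean of the two concentrations
#' reconstructs `c_tot` exactly.
#'
#' @param c_tot Total monomer concentration (>= 0).
#' @param gamma Monomer partition coefficient (> 0).
#' @param xi Partition degree, from [partition_degree()].
#' @return Named numeric vector `c(c_m_I, c_m_II)`.
#' @export
split_monomer_pool <- function(c_tot, gamma, xi) {
  if (!is.numeric(c_tot) || any(c_tot < 0)) {
    stop("c_tot must be a non-negative monomer concentration", call. = FALSE)
  }
  stopifnot(gamma > 0, xi > 0)
  c(c_m_I = xi * gamma * c_tot, c_m_II = xi * c_tot)
}
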