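#' Solver options for the kinetics integrators
#'
#' The two-compartment equations become stiff when the monomer exchange rate
#' far exceeds the aggregation rate, so the default integrator is `lsoda`
#' (switching to a BDF method in stiff regions) with a tight relative
#' tolerance. Output points are logarithmically spaced so that both the fast
#' exchange transient and the slow approach to the aggregation plateau are
#' resolved.
#'
#' @param rtol Relative tolerance (default `1e-8`).
#' @param atol Absolute tolerance; `NULL` (default) resolves to
#'   `1e-12 * m_tot` at integration time.
#' @param method Integration method passed to [deSolve::ode()].
#' @param n_out Number of logarithmically spaced output times (default 400).
#' @param t_min First positive output time as a fraction of `t_end`
#'   (default `1e-6`); `t = 0` is always included.
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(rtol = 1e-8, atol = NULL, method = "lsoda",
                           n_out = 400, t_min = 1e-6) {
  stopifnot(rtol > 0, is.null(atol) || atol > 0, n_out >= 10,
            t_min > 0, t_min < 1)
  structure(list(rtol = rtol, atol = atol, method = method,
                 n_out = n_out, t_min = t_min),
            class = "solver_options")
}

output_times <- function(t_end, opts) {
  c(0, exp(seq(log(opts$t_min * t_end), log(t_end), length.out = opts$n_out)))
}

#' Monomer exchange flux between the phases
#'
#' The diffusive flux that relaxes monomer partitioning back towards its
#' equilibrium value: `J = -k_exchange * (M_m^I - Gamma * M_m^II)`. Positive
#' `J` drives monomer mass into phase I, and the flux vanishes exactly at
#' partitioning equilibrium `M_m^I = Gamma * M_m^II`. There is no aggregation
#' at the interface, so the fluxes into the two phases balance:
#' `J^I = -J^II = J`.
#'
#' @param M_m_I,M_m_II Monomer mass concentrations in phases I and II (>= 0).
#' @param gamma Monomer partition coefficient (> 0).
#' @param k_exchange Relaxation rate (>= 0).
#' @return The signed flux J (mass per total volume per time).
#' @export
exchange_flux <- function(M_m_I, M_m_II, gamma, k_exchange) {
  stopifnot(all(M_m_I >= 0), all(M_m_II >= 0), gamma > 0, k_exchange >= 0)
  -k_exchange * (M_m_I - gamma * M_m_II)
}

# Phase-resolved rate constants (per-phase multipliers applied).
phase_rates <- function(rates, phase) {
  m <- rates$phase_multipliers[[phase]]
  list(k1 = rates$k1 * m[["k1"]], k2 = rates$k2 * m[["k2"]],
       k_plus = rates$k_plus * m[["k_plus"]],
       n1 = rates$n1, n2 = rates$n2)
}

# Core per-phase moment derivatives at monomer mass Mm.
moment_derivs <- function(c_a, M_a, M_m, pr) {
  M_m <- max(M_m, 0)
  list(
    dc_a = pr$k1 * M_m^pr$n1 + pr$k2 * M_m^pr$n2 * M_a,
    dM_a = 2 * pr$k_plus * M_m * c_a
  )
}

#' Time derivative of the two-compartment state
#'
#' Evaluates the moment equations in each phase: new fibrils form by primary
#' nucleation (`k1 * M_m^n1`) and aggregate-dependent secondary nucleation
#' (`k2 * M_m^n2 * M_a`); aggregate mass builds up by elongation at fibril
#' ends (`2 k_plus M_m c_a`); and the monomer balance combines depletion by
#' elongation with the inter-phase exchange flux `J / V^alpha` (per-phase
#' volumes `V^I = vI_frac * V`, `V^II = (1 - vI_frac) * V`, with `V = 1`).
#' The volume-weighted sum of all mass derivatives is zero, so total mass is
#' conserved.
#'
#' @param state A [system_state()].
#' @param rates A [kinetic_rates()].
#' @param gamma Monomer partition coefficient.
#' @return A list with components `phase_I`, `phase_II` (each with `dc_a`,
#'   `dM_a`, `dM_m`) and the flux `J`.
#' @export
aggregation_rhs <- function(state, rates, gamma) {
  validate_system_state(state)
  validate_kinetic_rates(rates)
  y <- c(state$phase_I$c_a, state$phase_I$M_a, state$phase_I$M_m,
         state$phase_II$c_a, state$phase_II$M_a, state$phase_II$M_m)
  p <- list(rates = rates, gamma = gamma, vI = state$vI_frac)
  d <- rhs_two_compartment(0, y, p)[[1]]
  J <- exchange_flux(state$phase_I$M_m, state$phase_II$M_m, gamma,
                     rates$k_exchange)
  list(phase_I = list(dc_a = d[1], dM_a = d[2], dM_m = d[3]),
       phase_II = list(dc_a = d[4], dM_a = d[5], dM_m = d[6]),
       J = J)
}

# deSolve rhs: y = (c_a_I, M_a_I, M_m_I, c_a_II, M_a_II, M_m_II)
rhs_two_compartment <- function(t, y, p) {
  if (any(!is.finite(y))) {
    stop("integration failure: non-finite state encountered at t = ", t,
         call. = FALSE)
  }
  prI <- phase_rates(p$rates, "I")
  prII <- phase_rates(p$rates, "II")
  dI <- moment_derivs(y[1], y[2], y[3], prI)
  dII <- moment_derivs(y[4], y[5], y[6], prII)
  J <- -p$rates$k_exchange * (y[3] - p$gamma * y[6])
  list(c(dI$dc_a, dI$dM_a, -dI$dM_a + J / p$vI,
         dII$dc_a, dII$dM_a, -dII$dM_a - J / (1 - p$vI)))
}

# deSolve rhs for the quasi-equilibrium (fast exchange) reduced model:
# y = (c_a_I, M_a_I, c_a_II, M_a_II, M_free) where M_free is the
# volume-weighted free monomer mass; the per-phase monomer pools are slaved
# to M_free through M_m_II = xi * M_free, M_m_I = gamma * xi * M_free with
# xi = 1 / (1 + (gamma - 1) * vI).
rhs_quasi_equilibrium <- function(t, y, p) {
  if (any(!is.finite(y))) {
    stop("integration failure: non-finite state encountered at t = ", t,
         call. = FALSE)
  }
  M_free <- max(y[5], 0)
  xi <- 1 / (1 + (p$gamma - 1) * p$vI)
  MmII <- xi * M_free
  MmI <- p$gamma * MmII
  prI <- phase_rates(p$rates, "I")
  prII <- phase_rates(p$rates, "II")
  dI <- moment_derivs(y[1], y[2], MmI, prI)
  dII <- moment_derivs(y[3], y[4], MmII, prII)
  list(c(dI$dc_a, dI$dM_a, dII$dc_a, dII$dM_a,
         -p$vI * dI$dM_a - (1 - p$vI) * dII$dM_a))
}

# deSolve rhs for the homogeneous single-compartment system;
# y = (c_a, M_a, M_m). With constant_monomer = TRUE the monomer pool is
# frozen (depletion switched off), yielding the linear early-time system.
rhs_homogeneous <- function(t, y, p) {
  if (any(!is.finite(y))) {
    stop("integration failure: non-finite state encountered at t = ", t,
         call. = FALSE)
  }
  d <- moment_derivs(y[1], y[2], y[3], p$pr)
  dMm <- if (p$constant_monomer) 0 else -d$dM_a
  list(c(d$dc_a, d$dM_a, dMm))
}

# Shared post-processing: negative-value guard and clipping.
guard_negative <- function(mat, m_tot, atol) {
  floor_neg <- -max(1e-14 * m_tot, 100 * atol)
  if (min(mat) < floor_neg) {
    stop(sprintf(
      "solver failure: state undershoot to %.3e (below the clipping floor %.3e); tighten tolerances or rescale the problem",
      min(mat), floor_neg), call. = FALSE)
  }
  mat[mat < 0] <- 0
  mat
}

new_trajectory <- function(df, model, rates, gamma, vI_frac, conserved_mass,
                           solver, t_end) {
  structure(df,
            class = c("aggregation_trajectory", "data.frame"),
            model = model, rates = rates, gamma = gamma, vI_frac = vI_frac,
            conserved_mass = conserved_mass, solver = solver, t_end = t_end)
}

#' @export
print.aggregation_trajectory <- function(x, ...) {
  cat(sprintf("Aggregation trajectory (%s model), %d time points, t_end = %g\n",
              attr(x, "model"), nrow(x), attr(x, "t_end")))
  cat(sprintf("  conserved mass m_tot = %g, max |mass residual| = %.3g\n",
              attr(x, "conserved_mass"), max(abs(x$mass_residual))))
  print.data.frame(utils::head(as.data.frame(x), 4))
  cat("  ...\n")
  invisible(x)
}

#' Simulate the two-compartment aggregation kinetics (finite exchange rate)
#'
#' Integrates the coupled moment equations for aggregate number, aggregate
#' mass and monomer mass in the condensed phase I and dilute phase II,
#' with the monomer exchange flux of [exchange_flux()] restoring the
#' partitioning equilibrium at rate `k_exchange`.
#'
#' @param initial A [system_state()], typically from
#'   [initial_state_at_partition_equilibrium()].
#' @param rates A [kinetic_rates()].
#' @param gamma Monomer partition coefficient (> 0), e.g. from
#'   [monomer_partition_coefficient()].
#' @param t_end Final integration time (> 0).
#' @param solver A [solver_options()].
#' @param times Optional explicit output times (overrides the default
#'   log-spaced grid); must be non-negative and strictly increasing.
#' @return An `aggregation_trajectory`: a data frame with columns
#'   `time, c_a_I, M_a_I, M_m_I, c_a_II, M_a_II, M_m_II, mass_residual`
#'   (the residual is the relative drift of the volume-weighted total mass),
#'   carrying the run metadata as attributes.
#' @examples
#' sp <- phase_spec(1, 0, 0.5, delta_chi = log(3))
#' st <- initial_state_at_partition_equilibrium(1, sp)
#' tr <- simulate_compartments(st, kinetic_rates(), gamma = 3, t_end = 20)
#' max(abs(tr$mass_residual)) < 1e-6
#' @export
simulate_compartments <- function(initial, rates, gamma, t_end,
                                  solver = solver_options(), times = NULL) {
  validate_system_state(initial)
  validate_kinetic_rates(rates)
  stopifnot(gamma > 0, t_end > 0)
  m_tot <- total_mass_density(initial)
  atol <- if (is.null(solver$atol)) 1e-12 * max(m_tot, .Machine$double.eps) else solver$atol
  if (is.null(times)) times <- output_times(t_end, solver)
  y0 <- c(initial$phase_I$c_a, initial$phase_I$M_a, initial$phase_I$M_m,
          initial$phase_II$c_a, initial$phase_II$M_a, initial$phase_II$M_m)
  p <- list(rates = rates, gamma = gamma, vI = initial$vI_frac)
  out <- deSolve::ode(y = y0, times = times, func = rhs_two_compartment,
                      parms = p, method = solver$method,
                      rtol = solver$rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("stiff-solver failure in simulate_compartments; ",
         "consider tighter tolerances or nondimensionalize() the rates",
         call. = FALSE)
  }
  y <- guard_negative(unname(out[, -1, drop = FALSE]), m_tot, atol)
  vI <- initial$vI_frac
  mass <- vI * (y[, 2] + y[, 3]) + (1 - vI) * (y[, 5] + y[, 6])
  df <- data.frame(time = out[, 1],
                   c_a_I = y[, 1], M_a_I = y[, 2], M_m_I = y[, 3],
                   c_a_II = y[, 4], M_a_II = y[, 5], M_m_II = y[, 6],
                   mass_residual = (mass - m_tot) / m_tot)
  new_trajectory(df, "finite_exchange", rates, gamma, vI, m_tot, solver, t_end)
}

#' Simulate the fast-exchange (quasi-equilibrium) reduced model
#'
#' In the limit of fast monomer exchange the partitioning equilibrium
#' `M_m^I = Gamma * M_m^II` holds at every instant; the monomer pools are
#' then slaved to the volume-weighted free monomer mass and the system
#' reduces to five state variables. This is the limit of
#' [simulate_compartments()] as `k_exchange -> Inf` and the default model
#' for parameter sweeps.
#'
#' @inheritParams simulate_compartments
#' @return An `aggregation_trajectory` with the same columns as
#'   [simulate_compartments()]; the stored monomer columns satisfy
#'   `M_m_I = gamma * M_m_II` exactly at every time point.
#' @export
simulate_quasi_equilibrium <- function(initial, rates, gamma, t_end,
                                       solver = solver_options(),
                                       times = NULL) {
  validate_system_state(initial)
  validate_kinetic_rates(rates)
  stopifnot(gamma > 0, t_end > 0)
  m_tot <- total_mass_density(initial)
  vI <- initial$vI_frac
  atol <- if (is.null(solver$atol)) 1e-12 * max(m_tot, .Machine$double.eps) else solver$atol
  if (is.null(times)) times <- output_times(t_end, solver)
  M_free0 <- vI * initial$phase_I$M_m + (1 - vI) * initial$phase_II$M_m
  y0 <- c(initial$phase_I$c_a, initial$phase_I$M_a,
          initial$phase_II$c_a, initial$phase_II$M_a, M_free0)
  p <- list(rates = rates, gamma = gamma, vI = vI)
  out <- deSolve::ode(y = y0, times = times, func = rhs_quasi_equilibrium,
                      parms = p, method = solver$method,
                      rtol = solver$rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("stiff-solver failure in simulate_quasi_equilibrium", call. = FALSE)
  }
  y <- guard_negative(unname(out[, -1, drop = FALSE]), m_tot, atol)
  xi <- partition_degree(gamma, vI)
  MmII <- xi * y[, 5]
  MmI <- gamma * MmII
  mass <- vI * (y[, 2] + MmI) + (1 - vI) * (y[, 4] + MmII)
  df <- data.frame(time = out[, 1],
                   c_a_I = y[, 1], M_a_I = y[, 2], M_m_I = MmI,
                   c_a_II = y[, 3], M_a_II = y[, 4], M_m_II = MmII,
                   mass_residual = (mass - m_tot) / m_tot)
  new_trajectory(df, "quasi_equilibrium", rates, gamma, vI, m_tot, solver,
                 t_end)
}

#' Simulate homogeneous (single-compartment) aggregation
#'
#' The reference system without compartments: the standard
#' nucleation--elongation moment equations in one well-mixed volume. This is
#' the limit of equal phase compositions (`Gamma = 1`), against which
#' enrichment and depletion in the two-phase system are measured.
#'
#' @param c_tot Initial monomer concentration.
#' @param rates A [kinetic_rates()] (the exchange rate is ignored).
#' @param t_end Final integration time.
#' @param solver A [solver_options()].
#' @param mm Monomer mass (default 1).
#' @param constant_monomer If `TRUE`, monomer depletion is switched off
#'   (the monomer pool is held at its initial value), which reduces the
#'   moment equations to the linear early-time system with closed-form
#'   solution `M_a(t) = (alpha/kappa^2) (cosh(kappa t) - 1)` where
#'   `alpha = 2 k_plus k1 M_m^(n1+1)` and `kappa^2 = 2 k_plus k2 M_m^(n2+1)`.
#' @param times Optional explicit output times.
#' @return An `aggregation_trajectory` with columns
#'   `time, c_a, M_a, M_m, mass_residual`.
#' @export
simulate_homogeneous <- function(c_tot, rates, t_end,
                                 solver = solver_options(), mm = 1,
                                 constant_monomer = FALSE, times = NULL) {
  validate_kinetic_rates(rates)
  stopifnot(c_tot >= 0, t_end > 0, mm > 0)
  m_tot <- c_tot * mm
  atol <- if (is.null(solver$atol)) 1e-12 * max(m_tot, .Machine$double.eps) else solver$atol
  if (is.null(times)) times <- output_times(t_end, solver)
  pr <- list(k1 = rates$k1, k2 = rates$k2, k_plus = rates$k_plus,
             n1 = rates$n1, n2 = rates$n2)
  p <- list(pr = pr, constant_monomer = constant_monomer)
  out <- deSolve::ode(y = c(0, 0, m_tot), times = times,
                      func = rhs_homogeneous, parms = p,
                      method = solver$method, rtol = solver$rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("stiff-solver failure in simulate_homogeneous", call. = FALSE)
  }
  y <- guard_negative(unname(out[, -1, drop = FALSE]), max(m_tot, 1), atol)
  mass <- y[, 2] + y[, 3]
  residual <- if (m_tot > 0 && !constant_monomer) (mass - m_tot) / m_tot else mass * 0
  df <- data.frame(time = out[, 1], c_a = y[, 1], M_a = y[, 2], M_m = y[, 3],
                   mass_residual = residual)
  new_trajectory(df, if (constant_monomer) "homogeneous_constant_monomer" else "homogeneous",
                 rates, 1, 1, m_tot, solver, t_end)
}

#' Long-time (plateau) readout of a trajectory
#'
#' Extracts the asymptotic per-phase aggregate concentrations from a
#' trajectory, with an explicit convergence certificate. A run is converged
#' when either (a) the free monomer pool has been exhausted (volume-weighted
#' monomer mass below `monomer_tol` of its initial value) -- the readout is
#' then taken at the exhaustion time itself, interpolated between output
#' points, which keeps the aggregate number well-defined for fragmenting
#' systems (`n2 = 0`), whose number concentration never stops growing in a
#' moment-closure description -- or
#' (b) the total aggregate number changed by less than `plateau_tol`
#' (relative) over the final decade of time. Transients are never returned
#' silently: an unconverged trajectory raises an error unless
#' `on_fail = "na"`.
#'
#' @param traj An `aggregation_trajectory`.
#' @param plateau_tol Relative change of the aggregate number over the final
#'   decade of time below which the run counts as plateaued (default `1e-3`).
#' @param monomer_tol Fraction of the initial monomer mass below which the
#'   monomer pool counts as exhausted (default `1e-6`).
#' @param on_fail `"error"` (default) or `"na"`: what to do when no plateau
#'   is certified.
#' @return A list of class `asymptotic_summary` with per-phase `c_a_inf`,
#'   `M_a_inf` (for two-compartment runs: `c_a_I_inf`, `M_a_I_inf`,
#'   `c_a_II_inf`, `M_a_II_inf`), `vI_frac`, `gamma`, `t_readout`,
#'   `converged`, and the certificate (`criterion`, `plateau_change`,
#'   `monomer_fraction`).
#' @export
asymptotic_readout <- function(traj, plateau_tol = 1e-3, monomer_tol = 1e-6,
                               on_fail = c("error", "na")) {
  on_fail <- match.arg(on_fail)
  stopifnot(inherits(traj, "aggregation_trajectory"))
  model <- attr(traj, "model")
  vI <- attr(traj, "vI_frac")
  m_tot <- attr(traj, "conserved_mass")
  two_phase <- model %in% c("finite_exchange", "quasi_equilibrium")
  if (two_phase) {
    Mm_tot <- vI * traj$M_m_I + (1 - vI) * traj$M_m_II
    ca_tot <- vI * traj$c_a_I + (1 - vI) * traj$c_a_II
  } else {
    Mm_tot <- traj$M_m
    ca_tot <- traj$c_a
  }
  n <- nrow(traj)
  t_end <- traj$time[n]
  monomer_frac <- Mm_tot / max(m_tot, .Machine$double.eps)
  exhausted <- which(monomer_frac <= monomer_tol)
  # plateau certificate over the final decade of time
  i_dec <- which(traj$time >= t_end / 10)[1]
  plateau_change <- if (ca_tot[n] > 0) {
    abs(ca_tot[n] - ca_tot[i_dec]) / ca_tot[n]
  } else 0
  interp <- NULL
  if (length(exhausted) > 0) {
    idx <- exhausted[1]
    criterion <- "monomer_exhaustion"
    converged <- TRUE
    if (idx > 1 && monomer_frac[idx - 1] > monomer_tol) {
      # locate the exact threshold crossing: the monomer pool decays
      # roughly exponentially, so interpolate its logarithm in time
      f0 <- monomer_frac[idx - 1]
      f1 <- max(monomer_frac[idx], .Machine$double.xmin)
      s <- (log(monomer_tol) - log(f0)) / (log(f1) - log(f0))
      s <- min(max(s, 0), 1)
      t0 <- traj$time[idx - 1]
      t1 <- traj$time[idx]
      interp <- list(idx0 = idx - 1, idx1 = idx, s = s,
                     t = t0 + s * (t1 - t0))
    }
  } else if (plateau_change < plateau_tol) {
    idx <- n
    criterion <- "plateau"
    converged <- TRUE
  } else {
    if (on_fail == "error") {
      stop(sprintf(
        "trajectory not converged: monomer fraction %.3g > %g and aggregate number still changed by %.3g over the final time decade (tolerance %g); increase t_end",
        monomer_frac[n], monomer_tol, plateau_change, plateau_tol),
        call. = FALSE)
    }
    idx <- n
    criterion <- "none"
    converged <- FALSE
  }
  value_at <- function(col) {
    if (!converged) return(NA_real_)
    if (is.null(interp)) return(traj[[col]][idx])
    v0 <- traj[[col]][interp$idx0]
    v1 <- traj[[col]][interp$idx1]
    v0 + interp$s * (v1 - v0)
  }
  t_readout <- if (!is.null(interp)) interp$t else traj$time[idx]
  base <- list(converged = converged, criterion = criterion,
               t_readout = t_readout,
               plateau_change = plateau_change,
               monomer_fraction = monomer_frac[idx],
               gamma = attr(traj, "gamma"), vI_frac = vI,
               model = model, m_tot = m_tot)
  vals <- if (two_phase) {
    list(c_a_I_inf = value_at("c_a_I"), M_a_I_inf = value_at("M_a_I"),
         c_a_II_inf = value_at("c_a_II"), M_a_II_inf = value_at("M_a_II"))
  } else {
    list(c_a_inf = value_at("c_a"), M_a_inf = value_at("M_a"))
  }
  structure(c(vals, base), class = "asymptotic_summary")
}

#' @export
print.asymptotic_summary <- function(x, ...) {
  cat("Asymptotic readout (", x$model, " model)\n", sep = "")
  cat(sprintf("  converged: %s (%s), t_readout = %g\n",
              x$converged, x$criterion, x$t_readout))
  if (!is.null(x$c_a_I_inf)) {
    cat(sprintf("  c_a_I(inf) = %.6g, c_a_II(inf) = %.6g, ratio = %.6g\n",
                x$c_a_I_inf, x$c_a_II_inf, x$c_a_I_inf / x$c_a_II_inf))
  } else {
    cat(sprintf("  c_a(inf) = %.6g, M_a(inf) = %.6g\n",
                x$c_a_inf, x$M_a_inf))
  }
  invisible(x)
}

#' Run a simulation until the plateau is reached
#'
#' Convenience wrapper that integrates with increasing `t_end` (doubling up
#' to `max_doublings` times) until [asymptotic_readout()] certifies
#' convergence.
#'
#' @param sim_fun One of [simulate_compartments()],
#'   [simulate_quasi_equilibrium()]; called as `sim_fun(initial, rates,
#'   gamma, t_end, solver)`.
#' @param initial,rates,gamma,solver Passed through to `sim_fun`.
#' @param t_end Initial guess for the integration horizon.
#' @param max_doublings Maximum number of times `t_end` is doubled.
#' @param plateau_tol,monomer_tol Passed to [asymptotic_readout()].
#' @return A list with `trajectory` and `summary` (the certified readout).
#' @export
run_to_plateau <- function(sim_fun, initial, rates, gamma, t_end,
                           solver = solver_options(), max_doublings = 6,
                           plateau_tol = 1e-3, monomer_tol = 1e-6) {
  for (i in seq_len(max_doublings + 1)) {
    traj <- sim_fun(initial, rates, gamma, t_end, solver)
    summ <- asymptotic_readout(traj, plateau_tol = plateau_tol,
                               monomer_tol = monomer_tol, on_fail = "na")
    if (summ$converged) {
      return(list(trajectory = traj, summary = summ))
    }
    t_end <- 2 * t_end
  }
  # one final attempt that raises the informative not-converged error
  asymptotic_readout(traj, plateau_tol = plateau_tol,
                     monomer_tol = monomer_tol, on_fail = "error")
}
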