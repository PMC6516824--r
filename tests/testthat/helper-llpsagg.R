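# Shared fixtures for the test suite. All rates are in natural units
# (m_tot = 1, kappa = 1 for the default n2 = 2 set).

default_rates <- function(...) kinetic_rates(...)

# Coarser output grid for speed in tests that only need readouts.
fast_solver <- function(...) solver_options(n_out = 200, ...)

two_phase_init <- function(vI, c_tot = 1, gamma = NULL, phi_I = 1,
                           phi_II = 0) {
  sp <- phase_spec(phi_I, phi_II, phi_II + vI * (phi_I - phi_II))
  initial_state_at_partition_equilibrium(c_tot, sp)
}

# Converged epsilon = c_a^I(inf)/c_a^II(inf) from a quasi-equilibrium run.
epsilon_sim <- function(gamma, vI, n1 = 2, n2 = 2, t_end = 40,
                        rates = kinetic_rates(n1 = n1, n2 = n2)) {
  init <- two_phase_init(vI)
  s <- run_to_plateau(simulate_quasi_equilibrium, init, rates, gamma, t_end,
                      fast_solver())$summary
  s$c_a_I_inf / s$c_a_II_inf
}

loglog_slope <- function(y, x) {
  unname(stats::coef(stats::lm(log(y) ~ log(x)))[2])
}
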