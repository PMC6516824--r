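test_that("exchange flux restores partitioning equilibrium", {
  expect_equal(exchange_flux(3, 1, 3, 5), 0)
  expect_equal(exchange_flux(1, 1, 1, 5), 0)
  # direct evaluation: J = -k (Mm_I - Gamma Mm_II)
  expect_equal(exchange_flux(1, 1, 3, 2), 4)
  # positive flux drives monomers into the depleted condensed phase
  expect_gt(exchange_flux(0.5, 1, 3, 1), 0)
  expect_lt(exchange_flux(5, 1, 3, 1), 0)
})

test_that("the two-compartment right-hand side has the moment-equation structure", {
  rates <- default_rates()
  zero <- system_state(compartment_state(), compartment_state(), 0.4)
  d0 <- aggregation_rhs(zero, rates, 3)
  expect_equal(unlist(d0[c("phase_I", "phase_II")]),
               unlist(d0[c("phase_I", "phase_II")]) * 0)
  # symmetric system with Gamma = 1: identical per-phase derivatives, J = 0
  st <- system_state(compartment_state(c_a = 1e-5, M_a = 0.2, M_m = 0.8),
                     compartment_state(c_a = 1e-5, M_a = 0.2, M_m = 0.8),
                     0.3)
  d <- aggregation_rhs(st, rates, 1)
  expect_equal(d$phase_I, d$phase_II)
  expect_equal(d$J, 0)
  # volume-weighted mass production is zero for arbitrary states
  set.seed(7)
  for (i in 1:20) {
    st <- system_state(
      compartment_state(c_a = runif(1, 0, 1e-3), M_a = runif(1),
                        M_m = runif(1)),
      compartment_state(c_a = runif(1, 0, 1e-3), M_a = runif(1),
                        M_m = runif(1)),
      runif(1, 0.05, 0.95))
    d <- aggregation_rhs(st, rates, exp(runif(1, 0, 2)))
    v <- st$vI_frac
    total <- v * (d$phase_I$dM_a + d$phase_I$dM_m) +
      (1 - v) * (d$phase_II$dM_a + d$phase_II$dM_m)
    expect_equal(total, 0, tolerance = 1e-12)
  }
})

test_that("per-phase rate multipliers scale the corresponding processes", {
  pm <- list(I = c(k1 = 2, k2 = 3, k_plus = 0.5),
             II = c(k1 = 1, k2 = 1, k_plus = 1))
  r0 <- default_rates()
  r1 <- default_rates(phase_multipliers = pm)
  st <- system_state(compartment_state(c_a = 1e-4, M_a = 0.1, M_m = 0.5),
                     compartment_state(c_a = 1e-4, M_a = 0.1, M_m = 0.5),
                     0.5)
  d0 <- aggregation_rhs(st, r0, 1)
  d1 <- aggregation_rhs(st, r1, 1)
  expect_equal(d1$phase_II, d0$phase_II)
  expect_equal(d1$phase_I$dM_a, 0.5 * d0$phase_I$dM_a)
  expect_equal(d1$phase_I$dc_a,
               2 * r0$k1 * 0.5^r0$n1 + 3 * r0$k2 * 0.5^r0$n2 * 0.1)
})

test_that("nondimensionalization round-trips and branches correctly", {
  set.seed(11)
  for (i in 1:10) {
    r <- kinetic_rates(k1 = 10^runif(1, -10, -2), n1 = sample(1:3, 1),
                       k2 = 10^runif(1, -6, 0), n2 = sample(0:3, 1),
                       k_plus = 10^runif(1, 1, 5),
                       k_exchange = 10^runif(1, 0, 4))
    m <- 10^runif(1, -2, 2)
    nd <- nondimensionalize(r, m)
    back <- redimensionalize(nd, m)
    for (f in c("k1", "k2", "k_plus", "k_exchange")) {
      expect_equal(back[[f]], r[[f]], tolerance = 1e-12)
    }
    expect_equal(characteristic_rate(nd$rates, 1), 1, tolerance = 1e-12)
  }
  r <- default_rates()
  expect_equal(characteristic_rate(default_rates(k_plus = 4 * r$k_plus), 1),
               2 * characteristic_rate(r, 1))
  # fragmentation-free fallback scale lambda when k2 = 0
  r0 <- default_rates(k2 = 0)
  expect_equal(characteristic_rate(r0, 1), sqrt(2 * r0$k_plus * r0$k1))
  expect_error(characteristic_rate(default_rates(k1 = 0, k2 = 0), 1),
               "characteristic")
})

test_that("trajectories conserve mass, stay positive, and grow monotonically", {
  rates <- default_rates()
  init <- two_phase_init(0.3)
  tr <- simulate_compartments(init, rates, 3, 20, fast_solver())
  expect_lt(max(abs(tr$mass_residual)), 1e-6)
  expect_true(all(as.matrix(tr[, 2:7]) >= 0))
  for (col in c("c_a_I", "M_a_I", "c_a_II", "M_a_II")) {
    expect_true(all(diff(tr[[col]]) >= -1e-12 * max(tr[[col]])))
  }
  # volume-weighted monomer mass is non-increasing
  mm <- 0.3 * tr$M_m_I + 0.7 * tr$M_m_II
  expect_true(all(diff(mm) <= 1e-12))
})

test_that("without nucleation, monomers only re-equilibrate between phases", {
  rates <- default_rates(k1 = 0, k2 = 0, k_exchange = 50)
  init <- system_state(compartment_state(M_m = 0.2),
                       compartment_state(M_m = 1), 0.4)
  tr <- simulate_compartments(init, rates, 3, 5)
  # no nucleation source: aggregate variables are (numerically) zero
  expect_lt(max(tr$c_a_I, tr$M_a_I, tr$c_a_II, tr$M_a_II), 1e-20)
  # relaxes to Mm_I = Gamma * Mm_II
  n <- nrow(tr)
  expect_equal(tr$M_m_I[n] / tr$M_m_II[n], 3, tolerance = 1e-6)
  expect_lt(max(abs(tr$mass_residual)), 1e-6)
})

test_that("a Gamma = 1 two-compartment run reproduces homogeneous kinetics", {
  rates <- default_rates()
  so <- solver_options(rtol = 1e-10)
  init <- system_state(compartment_state(M_m = 1),
                       compartment_state(M_m = 1), 0.5)
  tc <- simulate_compartments(init, rates, 1, 20, so)
  th <- simulate_homogeneous(1, rates, 20, so)
  for (pair in list(c("c_a_I", "c_a"), c("M_a_I", "M_a"), c("M_m_I", "M_m"),
                    c("c_a_II", "c_a"))) {
    a <- tc[[pair[1]]][-1]
    b <- th[[pair[2]]][-1]
    expect_lt(max(abs(a - b) / pmax(abs(b), .Machine$double.xmin)), 1e-6)
  }
})

test_that("homogeneous kinetics match early-time and closed-form oracles", {
  # purely primary-nucleated growth: c_a initially linear with slope k1 Mm^n1
  r1 <- default_rates(k2 = 0)
  tt <- c(0, 10^seq(-4, -2, length.out = 20))
  tr <- simulate_homogeneous(1, r1, 1e-2, times = tt)
  expect_equal(tr$c_a[-1] / (r1$k1 * tt[-1]), rep(1, 20), tolerance = 1e-3)
  # empty system stays empty
  tr0 <- simulate_homogeneous(0, default_rates(), 10)
  expect_true(all(as.matrix(tr0[, 2:4]) == 0))
  # mass conservation without flux: M_m + M_a = c_tot
  tr2 <- simulate_homogeneous(2, default_rates(), 20, fast_solver())
  expect_equal(tr2$M_m + tr2$M_a, rep(2, nrow(tr2)), tolerance = 1e-6)
  # frozen monomer pool: M_a(t) = (alpha/kappa^2) (cosh(kappa t) - 1)
  rates <- default_rates()
  tt <- seq(0.01, 3, length.out = 50)
  trc <- simulate_homogeneous(1, rates, 3,
                              solver_options(rtol = 1e-10, atol = 1e-20),
                              constant_monomer = TRUE, times = c(0, tt))
  alpha <- 2 * rates$k_plus * rates$k1
  kappa2 <- 2 * rates$k_plus * rates$k2
  expected <- (alpha / kappa2) * (cosh(sqrt(kappa2) * tt) - 1)
  expect_lt(max(abs(trc$M_a[-1] - expected) / expected), 1e-6)
})

test_that("asymptotic readout certifies convergence and refuses transients", {
  rates <- default_rates()
  init <- two_phase_init(0.3)
  # transient: integration stopped far before the plateau
  short <- simulate_quasi_equilibrium(init, rates, 3, 0.5)
  expect_error(asymptotic_readout(short), "not converged")
  expect_false(asymptotic_readout(short, on_fail = "na")$converged)
  # converged run: values stable under doubling of t_end
  s1 <- asymptotic_readout(simulate_quasi_equilibrium(init, rates, 3, 20))
  s2 <- asymptotic_readout(simulate_quasi_equilibrium(init, rates, 3, 40))
  expect_true(s1$converged)
  expect_equal(s1$c_a_I_inf, s2$c_a_I_inf, tolerance = 1e-3)
  expect_equal(s1$c_a_II_inf, s2$c_a_II_inf, tolerance = 1e-3)
  # monomer exhaustion: aggregate mass accounts for the initial monomers
  expect_equal(0.3 * s1$M_a_I_inf + 0.7 * s1$M_a_II_inf, 1,
               tolerance = 1e-4)
  # no nucleation: readout is identically zero via the plateau certificate
  quiet <- simulate_compartments(two_phase_init(0.4),
                                 default_rates(k1 = 0, k2 = 0), 2, 5)
  s0 <- asymptotic_readout(quiet)
  expect_true(s0$converged)
  expect_lt(abs(s0$c_a_I_inf), 1e-20)
  expect_lt(abs(s0$c_a_II_inf), 1e-20)
})

test_that("run_to_plateau extends the horizon until convergence", {
  rates <- default_rates()
  init <- two_phase_init(0.3)
  out <- run_to_plateau(simulate_quasi_equilibrium, init, rates, 2,
                        t_end = 1, max_doublings = 8)
  expect_true(out$summary$converged)
  direct <- asymptotic_readout(
    simulate_quasi_equilibrium(init, rates, 2, 64))
  expect_equal(out$summary$c_a_I_inf, direct$c_a_I_inf, tolerance = 1e-3)
})
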