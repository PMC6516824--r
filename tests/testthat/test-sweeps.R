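test_that("total and relative asymptotic concentrations combine per-phase readouts", {
  rates <- default_rates()
  init <- two_phase_init(0.5)
  s <- run_to_plateau(simulate_quasi_equilibrium, init, rates, 3,
                      40)$summary
  # volume-weighting check against direct recomputation
  expect_equal(total_asymptotic_concentration(s),
               0.5 * s$c_a_I_inf + 0.5 * s$c_a_II_inf)
  expect_equal(total_asymptotic_concentration(s, vI_frac = 0.2),
               0.2 * s$c_a_I_inf + 0.8 * s$c_a_II_inf)
  expect_equal(relative_asymptotic_concentration(2, 2), 0)
  expect_equal(relative_asymptotic_concentration(3, 2), 0.5)
  expect_error(relative_asymptotic_concentration(1, 0), "ca_hom")
  # refusing transients
  short <- asymptotic_readout(
    simulate_quasi_equilibrium(init, rates, 3, 0.5), on_fail = "na")
  expect_error(total_asymptotic_concentration(short), "not converged")
})

test_that("a degenerate 1x1 sweep reproduces a standalone simulation", {
  rates <- default_rates()
  sw <- sweep_partitioning(rates, gamma = 3, phi_bar = 0.3)
  expect_equal(nrow(sw$grid), 1)
  expect_true(sw$grid$converged)
  init <- two_phase_init(0.3)
  s <- run_to_plateau(simulate_quasi_equilibrium, init, rates, 3,
                      40)$summary
  expect_equal(sw$grid$ca_I_inf, s$c_a_I_inf, tolerance = 1e-10)
  expect_equal(sw$grid$epsilon, s$c_a_I_inf / s$c_a_II_inf,
               tolerance = 1e-10)
  hom <- asymptotic_readout(simulate_homogeneous(1, rates, 40))
  expect_equal(sw$ca_hom, hom$c_a_inf, tolerance = 1e-10)
})

test_that("sweeps are deterministic and consistent with spot-check simulations", {
  rates <- default_rates()
  gam <- c(2, 5, 12)
  pb <- c(0.1, 0.5)
  sw1 <- sweep_partitioning(rates, gamma = gam, phi_bar = pb)
  sw2 <- sweep_partitioning(rates, gamma = gam, phi_bar = pb)
  expect_identical(sw1$grid, sw2$grid)
  expect_true(all(sw1$grid$converged))
  expect_true(all(is.finite(as.matrix(sw1$grid[, c("epsilon", "C",
                                                   "ca_tot")]))))
  # epsilon monotone increasing in Gamma along each phi_bar slice
  for (p in pb) {
    sl <- sw1$grid[sw1$grid$phi_bar == p, ]
    expect_true(all(diff(sl$epsilon[order(sl$gamma)]) > 0))
  }
  # spot-check two random grid points against standalone runs
  set.seed(3)
  for (i in sample(nrow(sw1$grid), 2)) {
    row <- sw1$grid[i, ]
    s <- run_to_plateau(simulate_quasi_equilibrium,
                        two_phase_init(row$vI_frac), rates, row$gamma,
                        40)$summary
    expect_equal(row$epsilon, s$c_a_I_inf / s$c_a_II_inf,
                 tolerance = 1e-6)
  }
})

test_that("sign boundaries are recovered from planted analytic grids", {
  # planted zero line: C(phi_bar, gamma) = log(gamma) - 2 phi_bar
  phi <- seq(0.1, 0.9, length.out = 9)
  gam <- exp(seq(log(1.05), log(20), length.out = 25))
  g <- expand.grid(phi_bar = phi, gamma = gam)
  g$C <- log(g$gamma) - 2 * g$phi_bar
  b <- extract_sign_boundary(list(grid = g))
  expect_equal(nrow(b), 9)
  # recovered within one grid cell of the analytic zero gamma = exp(2 phi)
  for (i in seq_len(nrow(b))) {
    truth <- exp(2 * b$phi_bar[i])
    cell <- diff(gam)[max(1, findInterval(truth, gam))]
    expect_lt(abs(b$gamma[i] - truth), cell)
  }
  # single-signed grids give an empty boundary
  g$C <- -abs(g$C) - 0.1
  expect_equal(nrow(extract_sign_boundary(list(grid = g))), 0)
})

test_that("literature systems classify by their reaction orders", {
  tmpl <- literature_systems_template()
  expect_true(all(c("name", "mechanism", "n1", "n2") %in% names(tmpl)))
  expect_true(all(c("Tau", "Ure2p", "IAPP") %in% tmpl$name))
  # reaction orders ship empty: they are experimental inputs
  expect_error(classify_literature_systems(tmpl), "incomplete")
  tmpl$n1 <- 2
  tmpl$n2 <- c(0, 0, 1, 0.5, 2, 3)
  out <- classify_literature_systems(tmpl)
  expect_identical(out$regime[out$n2 == 0],
                   rep("large-compartment-optimal", 2))
  expect_identical(out$regime[out$n2 == 1], "volume-independent")
  expect_identical(out$regime[out$n2 == 3], "small-compartment-optimal")
})
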