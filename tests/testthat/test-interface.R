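test_that("config validation rejects unknown keys and bad values", {
  expect_silent(validate_config(list(gamma = 3, n2 = 0)))
  expect_error(validate_config(list(gamm = 3)), "unknown config key")
  expect_error(validate_config(list(k1 = "fast")), "numeric")
  expect_error(validate_config(list(model = "magic")), "one of")
  expect_error(validate_config(list(t_end = c(1, 2))), "single value")
})

test_that("resolving a config derives gamma, t_end and the compartment volume", {
  full <- resolve_config(list(phi_I = 1, phi_II = 0, phi_bar = 0.25,
                              delta_chi = log(3)))
  expect_equal(full$gamma, 3)
  expect_equal(attr(full, "vI_frac"), 0.25)
  expect_equal(full$t_end, 40 / attr(full, "kappa"))
  # explicit gamma overrides the thermodynamic value
  full2 <- resolve_config(list(delta_chi = log(3), gamma = 7))
  expect_equal(full2$gamma, 7)
})

test_that("configs round-trip through JSON files", {
  cfg <- list(model = "finite_exchange", gamma = 4, n2 = 0, phi_bar = 0.2)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back[names(cfg)], cfg)
})

test_that("run_simulation writes trajectory, summary and resolved config", {
  out_dir <- withr::local_tempdir()
  fx <- make_fixtures()
  res <- run_simulation(c(fx$fig3, list(n_out = 150)), out_dir = out_dir,
                        quiet = TRUE)
  expect_true(res$summary$converged)
  # the condensed phase ends up with more aggregates
  expect_gt(res$summary$c_a_I_inf, res$summary$c_a_II_inf)
  expect_true(all(file.exists(res$files)))
  summ <- jsonlite::read_json(res$files[["summary"]])
  expect_identical(summ$model, "quasi_equilibrium")
  expect_equal(summ$gamma, 3)
  expect_true(is.numeric(summ$mass_residual_max))
  # trajectory CSV round-trips at full precision
  tr <- utils::read.csv(res$files[["trajectory"]])
  expect_identical(names(tr),
                   c("time", "c_a_I", "M_a_I", "M_m_I", "c_a_II", "M_a_II",
                     "M_m_II", "mass_residual"))
  expect_equal(tr$c_a_I, res$trajectory$c_a_I)
  # resolved config re-runs to identical outputs
  res2 <- run_simulation(res$files[["config"]], quiet = TRUE)
  expect_identical(res2$trajectory$c_a_I, res$trajectory$c_a_I)
})

test_that("a homogeneous-composition run shows no compartment effect", {
  res <- run_simulation(list(gamma = 1, phi_bar = 0.5, n_out = 150),
                        quiet = TRUE)
  hom <- run_simulation(list(model = "homogeneous", n_out = 150),
                        quiet = TRUE)
  ca_tot <- total_asymptotic_concentration(res$summary)
  C <- relative_asymptotic_concentration(ca_tot, hom$summary$c_a_inf)
  expect_equal(C, 0, tolerance = 1e-4)
})

test_that("run_sweep exports deterministic long-format CSV", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(n2 = 0, sweep_gamma_n = 3, sweep_phi_bar_n = 3,
              sweep_gamma_min = 1.5, n_out = 150)
  r1 <- run_sweep(cfg, out_dir = out1, quiet = TRUE)
  r2 <- run_sweep(cfg, out_dir = out2, quiet = TRUE)
  expect_identical(readLines(r1$files[["sweep"]]),
                   readLines(r2$files[["sweep"]]))
  g <- utils::read.csv(r1$files[["sweep"]])
  expect_identical(names(g),
                   c("phi_bar", "gamma", "vI_frac", "epsilon", "C", "ca_tot",
                     "ca_I_inf", "ca_II_inf", "converged"))
  expect_true(all(g$converged))
  expect_true(all(is.finite(g$epsilon)))
  meta <- jsonlite::read_json(r1$files[["metadata"]])
  expect_equal(length(meta$gamma_grid), 3)
})

test_that("fixtures are stable, schema-valid, and runnable", {
  fx <- make_fixtures()
  expect_identical(names(fx),
                   c("fig3", "fig3e_primary", "fig3e_secondary", "fig5a",
                     "fig5bc", "boundary"))
  for (cfg in fx) expect_silent(validate_config(cfg))
  expect_equal(resolve_config(fx$fig5bc)$n2, 3)
  expect_equal(resolve_config(fx$fig3)$gamma, 3)
  dir <- withr::local_tempdir()
  make_fixtures(dir)
  expect_identical(sort(list.files(dir)),
                   sort(paste0(names(fx), ".json")))
})
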