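test_that("flux-force efficacy reproduces the 80% calibration point", {
  expect_equal(flux_force_efficacy(5.45, 298.15), 0.800, tolerance = 0.001)
  expect_identical(flux_force_efficacy(0), 0)
  expect_equal(flux_force_efficacy(2.4788, 298.15), tanh(0.5),
               tolerance = 1e-4)
})

test_that("efficacy equals tanh(dG/2RT) and is odd, bounded, increasing", {
  x <- seq(-80, 80, length.out = 401)
  RT <- 8.314462618e-3 * 298.15
  expect_equal(flux_force_efficacy(x), tanh(x / (2 * RT)), tolerance = 1e-15)
  expect_equal(flux_force_efficacy(-x), -flux_force_efficacy(x))
  expect_true(all(abs(flux_force_efficacy(x)) < 1))
  expect_true(all(diff(flux_force_efficacy(x)) > 0))
  # numerically stable far into saturation
  xs <- seq(-500, 500, length.out = 201)
  expect_true(all(is.finite(flux_force_efficacy(xs))))
  expect_true(all(abs(flux_force_efficacy(xs)) <= 1))
  expect_true(all(diff(flux_force_efficacy(xs)) >= 0))
})

test_that("mdf_for_ffe inverts the efficacy", {
  expect_equal(mdf_for_ffe(0.80, 298.15), 5.45, tolerance = 0.01)
  expect_identical(mdf_for_ffe(0), 0)
  expect_equal(mdf_for_ffe(0.4621, 298.15), 2.4788, tolerance = 1e-3)
  dG <- seq(0, 30, by = 1)
  expect_equal(mdf_for_ffe(flux_force_efficacy(dG)), dG, tolerance = 1e-9)
  dG2 <- seq(30, 60, by = 5)  # deep saturation: reduced relative precision
  expect_equal(mdf_for_ffe(flux_force_efficacy(dG2)), dG2, tolerance = 1e-3)
  expect_error(mdf_for_ffe(1), "ffe")
})

test_that("equilibrium constants fold in substrate-level phosphorylation", {
  env <- env_conditions()
  RT <- 8.314462618e-3 * 298.15
  expect_equal(ln_equilibrium_constant(list(dG0_prime = 0, slp_atp = 0), env), 0)
  expect_equal(ln_equilibrium_constant(
    list(dG0_prime = -RT * log(10), slp_atp = 0), env), log(10))
  # forming one ATP worth 50 kJ/mol cancels a -50 kJ/mol step exactly
  expect_equal(ln_equilibrium_constant(
    list(dG0_prime = -50, slp_atp = 1), env_conditions(dG_ATP = 50)), 0)
  # consuming one ATP makes the step more favorable by the same amount
  expect_equal(ln_equilibrium_constant(
    list(dG0_prime = -50, slp_atp = -1), env_conditions(dG_ATP = 50)),
    100 / (8.314462618e-3 * 298.15))
})

test_that("dimensionless potentials follow Phi = -FE/RT", {
  expect_identical(nernst_phi(0), 0)
  expect_equal(nernst_phi(-0.414, 298.15), 16.12, tolerance = 0.05 / 16)
  E <- c(-0.5, -0.1, 0.2)
  expect_equal(nernst_phi(2 * E), 2 * nernst_phi(E))
  expect_equal(phi_to_volts(nernst_phi(E)), E, tolerance = 1e-12)
})

test_that("environmental defaults give pmf 15 kJ/mol and a CPT cap of 3", {
  env <- env_conditions()
  expect_equal(env$pmf_per_proton, 15)
  expect_identical(env$cpt_cap, 3L)
  expect_error(env_conditions(conc_CO2 = -1))
})
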