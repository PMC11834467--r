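# Condition scans: cost grids and trade-off sweeps.

test_that("ATP cost never rises with more electron donor", {
  grid <- atp_cost_grid(pathway_fixture("rtca"),
                        log10_co2 = c(-3, -2), log10_h2 = seq(-4, -1, by = 1))
  for (lc in unique(grid$log10_co2)) {
    row <- grid[grid$log10_co2 == lc & grid$feasible, ]
    row <- row[order(row$log10_h2), ]
    expect_true(all(diff(row$atp_cost_per_CO2) <= 1e-9))
  }
  expect_true(all(diff(unique(grid$E_donor_V)) < 0))  # donor axis mapping
})

test_that("an imposed driving-force floor can only raise the ATP cost", {
  free <- atp_cost_grid(pathway_fixture("rtca"), log10_co2 = -2,
                        log10_h2 = c(-3, -2, -1))
  forced <- atp_cost_grid(pathway_fixture("rtca"), log10_co2 = -2,
                          log10_h2 = c(-3, -2, -1), imposed_mdf = 5.45)
  both <- free$feasible & forced$feasible
  expect_true(all(forced$atp_cost_per_CO2[both] >=
                    free$atp_cost_per_CO2[both] - 1e-9))
  expect_true(all(forced$feasible <= free$feasible))
})

test_that("sweeps show the sawtooth: CPT steps up, MDF drops at the step", {
  sp <- synthetic_spec(n_reactions = 3, total_dG0 = -35, cpt_sites = 2,
                       redox_steps = 3, carrier_sets = list("NAD"))
  p <- generate_pathway(sp)
  sw <- tradeoff_sweep(p, log10_h2 = seq(-6, -1, by = 0.25), epsilons = 0)
  sw <- sw[sw$feasible, ]
  expect_true(nrow(sw) >= 8)
  expect_true(all(diff(sw$total_cpt) >= 0))            # monotone recovery
  steps <- which(diff(sw$total_cpt) > 0)
  expect_true(length(steps) >= 1)
  for (i in steps) {
    expect_true(sw$mdf_kJ_mol[i + 1] < sw$mdf_kJ_mol[i])  # instantaneous drop
  }
  # between steps the MDF grows with the donor concentration
  flat <- which(diff(sw$total_cpt) == 0)
  expect_true(all(diff(sw$mdf_kJ_mol)[flat] > -1e-9))
})

test_that("trading translocations buys driving force pointwise on rTCA", {
  sw <- tradeoff_sweep(pathway_fixture("rtca"),
                       log10_h2 = c(-2.5, -2, -1.5, -1), epsilons = 0:2)
  for (lh in unique(sw$log10_h2)) {
    s <- sw[sw$log10_h2 == lh & sw$feasible, ]
    s <- s[order(s$epsilon), ]
    if (nrow(s) >= 2) {
      expect_true(all(diff(s$mdf_kJ_mol) >= -1e-9))
      expect_true(all(diff(s$atp_cost_per_CO2) >= -1e-9))
    }
  }
})

test_that("scan cells are pure functions of their conditions", {
  g1 <- atp_cost_grid(pathway_fixture("wl_acetogenic"), log10_co2 = -2,
                      log10_h2 = c(-2, -1))
  g2 <- atp_cost_grid(pathway_fixture("wl_acetogenic"), log10_co2 = -2,
                      log10_h2 = c(-2, -1))
  expect_identical(g1, g2)
})
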