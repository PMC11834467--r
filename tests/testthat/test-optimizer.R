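# Two-stage optimization: constraint building, both stages, variant choice.

test_that("constraint systems expose CPT sites and clamp species", {
  env <- env_conditions()
  sys <- build_system(first_variant(pathway_fixture("rtca")), env)
  # the three chemiosmotic recovery sites: reductions of OAA, fumarate, KGA
  expect_length(sys$cpt_idx, 3)
  expect_setequal(sys$reaction_ids[sys$cpt_idx],
                  c("oaa_red", "fum_red", "oxs_red"))
  expect_false(any(c("CO2", "H2", "H2O", "H+") %in% sys$var_ids))

  sys1 <- build_system(first_variant(single_reaction_pathway()), env)
  expect_identical(nrow(sys1$S), 1L)
  expect_length(sys1$cpt_idx, 0)
})

test_that("stage 1 recovers floor(available energy / pmf) translocations", {
  env <- env_conditions()  # pmf = 15 kJ/mol
  p <- single_reaction_pathway(dG0 = -40, cpt = TRUE)
  sys <- build_system(first_variant(p), env)
  s1 <- maximize_cpt(sys)
  expect_identical(s1$status, "optimal")
  expect_equal(s1$total_cpt, 2)  # floor(40 / 15)
  o <- brute_force_oracle(first_variant(p), env)
  expect_equal(o$total_cpt, 2)

  # +100 kJ/mol uphill with bounded concentrations is infeasible
  p2 <- single_reaction_pathway(dG0 = 100)
  expect_identical(maximize_cpt(build_system(first_variant(p2), env))$status,
                   "infeasible")

  # imposing an MDF keeps 2 CPT only because 40 - 2*15 >= 10
  s1b <- maximize_cpt(sys, imposed_mdf = 10)
  expect_equal(s1b$total_cpt, 2)
  s1c <- maximize_cpt(sys, imposed_mdf = 10.5)
  expect_equal(s1c$total_cpt, 1)
})

test_that("stage 2 partitions dissipation and trades translocations", {
  env <- env_conditions()
  # uniform 3-chain, D = 30, no CPT: equal partition at 10 kJ/mol
  r <- optimize_variant(first_variant(generate_pathway(chain3())), env)
  expect_equal(r$mdf_kJ_mol, 10, tolerance = 1e-9)

  # one CPT site: eps = 0 -> (30-15)/3 = 5; eps = 1 -> 10
  v <- first_variant(generate_pathway(chain3(cpt_site = 2)))
  r0 <- optimize_variant(v, env, epsilon = 0)
  r1 <- optimize_variant(v, env, epsilon = 1)
  expect_equal(r0$total_cpt, 1)
  expect_equal(r0$mdf_kJ_mol, 5, tolerance = 1e-9)
  expect_equal(r1$mdf_kJ_mol, 10, tolerance = 1e-9)

  # an unreachable epsilon is infeasible, not an error
  sys <- build_system(v, env)
  rbad <- maximize_mdf(sys, n_opt = 1, epsilon = 1 + 2 * env$cpt_cap)
  expect_identical(rbad$status, "infeasible")
})

test_that("ATP cost accounting matches the chemiosmotic bookkeeping", {
  env <- env_conditions(conc_H2 = 1e-1)
  p <- pathway_fixture("wl_methanogenic")
  b <- best_variant(p, env)
  r <- b$result
  expect_identical(r$status, "optimal")
  # SLP-free pathway: cost is -CPT/r_H_per_ATP per product over 2 CO2
  expect_equal(r$atp_cost_per_CO2,
               -r$total_cpt / env$r_H_per_ATP / 2, tolerance = 1e-9)
  # trading one translocation costs exactly 1/r_H_per_ATP per product
  v <- b$variant
  r1 <- optimize_variant(v, env, epsilon = 1)
  expect_equal(r1$atp_cost_per_CO2 - optimize_variant(v, env)$atp_cost_per_CO2,
               (1 / env$r_H_per_ATP) / 2, tolerance = 1e-9)
})

test_that("best variant prefers cheaper ATP, then larger MDF", {
  env <- env_conditions(conc_H2 = 1e-2)
  p1 <- single_reaction_pathway(dG0 = -40, cpt = TRUE)
  b <- best_variant(p1, env)
  expect_identical(b$index, 1L)

  # a carrier whose regeneration frees 10 kJ/mol at a CPT site wins
  sp <- synthetic_spec(n_reactions = 2, total_dG0 = -35,
                       cpt_sites = 1, redox_steps = 1,
                       carrier_sets = list(c("FAD", "NAD")))
  p2 <- generate_pathway(sp)
  b2 <- best_variant(p2, env)
  expect_identical(b2$result$status, "optimal")
  worst <- min(vapply(enumerate_variants(p2), function(v) {
    r <- optimize_variant(v, env)
    if (r$status == "optimal") -r$atp_cost_per_product else -Inf
  }, 0))
  expect_true(-b2$result$atp_cost_per_product >= worst)
})

test_that("the rTCA cycle undercuts the WL pathways in ATP cost", {
  env <- env_conditions(conc_CO2 = 1e-2, conc_H2 = 1e-1)
  costs <- vapply(c("rtca", "wl_acetogenic", "wl_methanogenic"),
                  function(id) {
                    best_variant(pathway_fixture(id), env)$result$atp_cost_per_CO2
                  }, 0)
  expect_true(costs[["rtca"]] <= costs[["wl_acetogenic"]])
  expect_true(costs[["rtca"]] <= costs[["wl_methanogenic"]])
})

test_that("stage-1 with an imposed MDF never beats the unconstrained stage 1", {
  env <- env_conditions(conc_H2 = 1e-2)
  for (id in c("rtca", "hp4hb")) {
    sys <- build_system(first_variant(pathway_fixture(id)), env)
    free <- maximize_cpt(sys)
    floor5 <- maximize_cpt(sys, imposed_mdf = 5.45)
    if (floor5$status == "optimal") {
      expect_true(floor5$total_cpt <= free$total_cpt)
    } else {
      succeed()
    }
  }
})
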