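# Carrier-free potential analysis: half-reaction systems, solution pools,
# optimal potential ranges and known-carrier matching.

test_that("potential systems carry one Phi per redox step plus donor halves", {
  env <- env_conditions(conc_H2 = 1e-2)
  sys <- build_potential_system(pathway_fixture("rtca"), env)
  expect_length(sys$phi_vars, 4)
  expect_setequal(sys$phi_reactions,
                  c("oaa_red", "fum_red", "kga_synth", "oxs_red"))
  expect_length(grep("^donor_", sys$reaction_ids), 4)

  sp <- synthetic_spec(n_reactions = 2, total_dG0 = -40, redox_steps = 1,
                       carrier_sets = list("NAD"))
  sys1 <- build_potential_system(generate_pathway(sp), env)
  expect_length(sys1$phi_vars, 1)
  expect_length(grep("^donor_", sys1$reaction_ids), 1)

  expect_error(build_potential_system(single_reaction_pathway(), env),
               "redox")
})

test_that("half plus donor reactions restore the hydrogen-form energetics", {
  env <- env_conditions(conc_H2 = 1e-2)
  p <- pathway_fixture("rtca")
  sys <- build_potential_system(p, env)
  v <- sys$variant
  for (rid in sys$phi_reactions) {
    total <- v$reactions[[rid]]$dG0_prime +
      v$reactions[[paste0("donor_", rid)]]$dG0_prime
    expect_equal(total, p$reactions[[rid]]$dG0_prime, tolerance = 1e-9)
  }
  # electrons cancel in the net transformation
  net <- overall_stoichiometry(v)
  expect_false(any(grepl("^e_", names(net$stoich))))
})

test_that("the solution pool lists all integer optima", {
  env <- env_conditions(conc_H2 = 1e-2)
  # symmetric chain: two identical CPT sites, energy for one proton;
  # clamps at the center of the concentration box keep the mirror symmetry
  sp <- synthetic_spec(n_reactions = 2, total_dG0 = -20, cpt_sites = c(1, 2),
                       clamp_sub = 1e-4, clamp_prod = 1e-4)
  sys <- build_system(first_variant(generate_pathway(sp)), env)
  pool <- enumerate_optimal_pool(sys)
  expect_identical(pool$n_opt, 1)
  expect_length(pool$pool, 2)
  sums <- vapply(pool$pool, sum, 0)
  expect_true(all(sums == pool$n_opt))

  # a plainly asymmetric system has a unique optimum
  sys1 <- build_potential_system(pathway_fixture("rtca"), env)
  pool1 <- enumerate_optimal_pool(sys1)
  expect_true(length(pool1$pool) >= 1)
  expect_true(all(vapply(pool1$pool, function(np)
    sum(sys1$flux[sys1$cpt_idx] * np), 0) == pool1$n_opt))
})

test_that("potential ranges are ordered, reproducible and bounded", {
  env <- env_conditions(conc_H2 = 1e-2)
  sys <- build_potential_system(pathway_fixture("rtca"), env)
  pool <- enumerate_optimal_pool(sys)
  widths <- c()
  for (rid in sys$phi_reactions) {
    pr <- phi_range(sys, pool, rid)
    expect_true(pr$E_min_V <= pr$E_max_V + 1e-12)
    expect_true(pr$E_min_V >= -0.6 - 1e-9 && pr$E_max_V <= 0.4 + 1e-9)
    pr2 <- phi_range(sys, pool, rid)
    expect_identical(pr, pr2)
    widths[rid] <- pr$E_max_V - pr$E_min_V
  }
  # the succinyl-CoA reduction runs in a narrow optimal window (< 100 mV)
  expect_true(widths[["kga_synth"]] < 0.1)
})

test_that("fixing a mid-range potential preserves the two-stage optimum", {
  env <- env_conditions(conc_H2 = 1e-2)
  p <- pathway_fixture("rtca")
  sys <- build_potential_system(p, env)
  pool <- enumerate_optimal_pool(sys)
  rid <- "oaa_red"
  pr <- phi_range(sys, pool, rid)
  mid <- (pr$phi_min + pr$phi_max) / 2
  sys2 <- sys
  col <- match(sys$phi_vars[[rid]], sys$var_ids)
  sys2$lnc_lower[col] <- mid
  sys2$lnc_upper[col] <- mid
  s1 <- maximize_cpt(sys2)
  expect_identical(s1$status, "optimal")
  expect_equal(s1$total_cpt, pool$n_opt)
  s2 <- maximize_mdf(sys2, n_opt = s1$total_cpt)
  expect_equal(s2$mdf_kJ_mol, pool$mdf_kJ_mol,
               tolerance = 1e-6 * max(1, abs(pool$mdf_kJ_mol)))
})

test_that("wider concentration bounds never narrow a potential range", {
  sp <- synthetic_spec(n_reactions = 3, total_dG0 = -50, redox_steps = 2,
                       carrier_sets = list("NAD"), cpt_sites = 1)
  p <- generate_pathway(sp)
  env_narrow <- env_conditions(conc_H2 = 1e-3, conc_bounds = c(1e-5, 1e-3))
  env_wide <- env_conditions(conc_H2 = 1e-3, conc_bounds = c(1e-6, 1e-2))
  rn <- local({
    sys <- build_potential_system(p, env_narrow)
    phi_range(sys, enumerate_optimal_pool(sys), "R02")
  })
  rw <- local({
    sys <- build_potential_system(p, env_wide)
    phi_range(sys, enumerate_optimal_pool(sys), "R02")
  })
  expect_true(rw$E_max_V - rw$E_min_V >= rn$E_max_V - rn$E_min_V - 1e-9)
})

test_that("known-carrier matching follows the Nernst window", {
  carriers <- list(new_carrier("NAD", -0.320),
                   new_carrier("hot", 0.0))
  # degenerate range exactly at a carrier's standard potential: ratio ~1
  r0 <- list(E_min_V = -0.320, E_max_V = -0.320)
  m <- match_known_carriers(r0, carriers["NAD" == vapply(carriers, `[[`, "", "id")])
  expect_true(m$compatible[1])
  expect_equal(m$ratio_lo[1], 1, tolerance = 1e-9)
  expect_equal(m$ratio_hi[1], 1, tolerance = 1e-9)
  # 200 mV above the window cannot be bridged by a 2-electron couple at
  # ratio <= 100 (max shift ~59 mV at 298 K)
  r1 <- list(E_min_V = -0.30, E_max_V = -0.20)
  m1 <- match_known_carriers(r1, carriers[2])
  expect_false(m1$compatible[1])
  # NAD reaches a window below -0.38 V only beyond ratio 100
  r2 <- list(E_min_V = -0.45, E_max_V = -0.40)
  m2 <- match_known_carriers(r2, carriers[1])
  expect_false(m2$compatible[1])
})
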