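# Synthetic pathway generator and its closed-form oracle.

test_that("generation is deterministic per seed", {
  sp <- synthetic_spec(n_reactions = 4, total_dG0 = -50, split = "random",
                       seed = 7)
  p1 <- generate_pathway(sp)
  p2 <- generate_pathway(sp)
  expect_identical(p1, p2)
  p3 <- generate_pathway(synthetic_spec(n_reactions = 4, total_dG0 = -50,
                                        split = "random", seed = 8))
  expect_false(identical(vapply(p1$reactions, `[[`, 0, "dG0_prime"),
                         vapply(p3$reactions, `[[`, 0, "dG0_prime")))
})

test_that("random splits sum to the requested total", {
  for (seed in 1:10) {
    sp <- synthetic_spec(n_reactions = 5, total_dG0 = -80, split = "random",
                         seed = seed)
    p <- generate_pathway(sp)
    expect_equal(sum(vapply(p$reactions, `[[`, 0, "dG0_prime")), -80,
                 tolerance = 1e-9)
  }
})

test_that("the analytic chain MDF covers clamps, CPT, SLP and redox", {
  env <- env_conditions()
  # base: D/n = 10
  expect_equal(analytic_mdf(chain3(), env), 10)
  # one recovered CPT at pmf 15: (30 - 15)/3 = 5
  expect_equal(analytic_mdf(chain3(), env, total_np = 1), 5)
  # an ATP-consuming step adds its hydrolysis energy: (30 + 50)/3
  sp <- synthetic_spec(n_reactions = 3, total_dG0 = -30,
                       slp_steps = c("1" = -1))
  expect_equal(analytic_mdf(sp, env), 80 / 3)
  # cycles are refused
  expect_error(analytic_mdf(synthetic_spec(topology = "cycle"), env),
               "chain")
})

test_that("optimizer reproduces the closed form on equal-split chains", {
  env <- env_conditions()
  cases <- list(
    chain3(),
    synthetic_spec(n_reactions = 5, total_dG0 = -60),
    synthetic_spec(n_reactions = 5, total_dG0 = -25)
  )
  for (sp in cases) {
    v <- first_variant(generate_pathway(sp))
    r <- optimize_variant(v, env)
    expect_identical(r$status, "optimal")
    expect_equal(r$mdf_kJ_mol, analytic_mdf(sp, env, total_np = r$total_cpt),
                 tolerance = 1e-6)
  }
  # an SLP step shifts its own equilibrium; keep the hydrolysis energy small
  # enough that the concentration box still allows equal partition
  env20 <- env_conditions(dG_ATP = 20)
  sp_slp <- synthetic_spec(n_reactions = 4, total_dG0 = -45,
                           slp_steps = c("3" = -1))
  r <- optimize_variant(first_variant(generate_pathway(sp_slp)), env20)
  expect_equal(r$mdf_kJ_mol, analytic_mdf(sp_slp, env20), tolerance = 1e-6)
  # with a carrier the regeneration step and ratio bounds bind instead;
  # the grid-refinement oracle is the reference there
  spr <- synthetic_spec(n_reactions = 3, total_dG0 = -55, redox_steps = 2,
                        carrier_sets = list("NAD"))
  vr <- first_variant(generate_pathway(spr))
  rr <- optimize_variant(vr, env)
  orr <- brute_force_oracle(vr, env)
  expect_equal(rr$total_cpt, orr$total_cpt)
  expect_equal(rr$mdf_kJ_mol, orr$mdf_kJ_mol, tolerance = 0.05)
})

test_that("seeded random chains agree with the closed form when bounds are slack", {
  env <- env_conditions()
  for (seed in 1:30) {
    set.seed(seed + 4000)
    n <- sample(2:5, 1)
    sp <- synthetic_spec(n_reactions = n, total_dG0 = -runif(1, 15, 50),
                         clamp_sub = 1e-3, clamp_prod = 1e-3, seed = seed)
    r <- optimize_variant(first_variant(generate_pathway(sp)), env)
    expect_identical(r$status, "optimal")
    expect_equal(r$mdf_kJ_mol, analytic_mdf(sp, env), tolerance = 1e-6)
  }
})
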