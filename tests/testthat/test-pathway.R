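# Pathway model: file I/O, validation, variant enumeration, aggregates.

minimal_pathway_json <- function(stoich_ok = TRUE) {
  tmp <- tempfile(fileext = ".json")
  x <- list(
    id = "mini", name = "minimal", oxygen_class = "anaerobic",
    metabolites = list(
      list(id = "A", carbon = 1, role = "clamped", clamp = 1e-3),
      list(id = "B", carbon = if (stoich_ok) 1 else 2, role = "internal")),
    carriers = list(),
    reactions = list(list(id = "R1", stoich = list(A = -1, B = 1),
                          dG0_prime_kJ_mol = -10, slp_atp = 0,
                          cpt_capable = FALSE)),
    end_product = "B",
    overall = list(stoich = list(A = -1, B = 1), dG0_prime_kJ_mol = -10),
    declared = list(slp_cost = 0, variants = 1, reactions = 1))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE)
  tmp
}

test_that("a minimal pathway file loads and validates", {
  p <- load_pathway(minimal_pathway_json())
  expect_s3_class(p, "pmdf_pathway")
  expect_length(p$reactions, 1)
  expect_identical(p$end_product, "B")
})

test_that("carbon imbalance is a validation error naming the reaction", {
  expect_error(load_pathway(minimal_pathway_json(stoich_ok = FALSE)),
               "R1.*carbon imbalance")
})

test_that("rational coefficients parse", {
  expect_identical(pathmdf:::parse_coef("1/2"), 0.5)
  expect_identical(pathmdf:::parse_coef("-3/2"), -1.5)
  expect_identical(pathmdf:::parse_coef(2L), 2)
  expect_error(pathmdf:::parse_coef("x"), "parse")
})

test_that("variant enumeration is the Cartesian product of carrier sets", {
  sp <- synthetic_spec(n_reactions = 4, total_dG0 = -40,
                       redox_steps = c(2, 3),
                       carrier_sets = list(c("NAD", "Fd"),
                                           c("NAD", "NADP", "FAD")))
  vs <- enumerate_variants(generate_pathway(sp))
  expect_length(vs, 6)
  assignments <- vapply(vs, function(v)
    paste(v$carrier_assignment, collapse = "|"), "")
  expect_length(unique(assignments), 6)
  # three carrier-set sizes {2, 3, 1}
  sp2 <- synthetic_spec(n_reactions = 4, total_dG0 = -40,
                        redox_steps = c(1, 2, 4),
                        carrier_sets = list(c("NAD", "Fd"),
                                            c("NAD", "NADP", "FAD"),
                                            "F420"))
  expect_length(enumerate_variants(generate_pathway(sp2)), 6)
})

test_that("net SLP cost is the negated flux-weighted slp_atp sum", {
  sp <- synthetic_spec(n_reactions = 3, total_dG0 = -30,
                       slp_steps = c("2" = -1))
  v <- first_variant(generate_pathway(sp))
  expect_equal(net_slp_cost(v), 1)
})

test_that("overall stoichiometry cancels carriers and intermediates", {
  p <- single_reaction_pathway()
  v <- first_variant(p)
  net <- overall_stoichiometry(v)
  expect_equal(net$stoich, list(A = -1, B = 1))
  # carrier choice never changes the net transformation
  sp <- synthetic_spec(n_reactions = 3, total_dG0 = -40, redox_steps = 2,
                       carrier_sets = list(c("NAD", "Fd")))
  vs <- enumerate_variants(generate_pathway(sp))
  nets <- lapply(vs, function(v) overall_stoichiometry(v)$stoich)
  expect_identical(nets[[1]][order(names(nets[[1]]))],
                   nets[[2]][order(names(nets[[2]]))])
  dgs <- vapply(vs, function(v) overall_stoichiometry(v)$dG0_prime, 0)
  expect_equal(dgs[1], dgs[2], tolerance = 1e-9)
})

test_that("a non-cancelling internal species is a closure error", {
  p <- single_reaction_pathway()
  v <- first_variant(p)
  # break closure: bolt on a reaction producing an orphan internal species
  v$metabolites[["X"]] <- pathmdf:::new_metabolite("X", carbon = 0)
  v$reactions[["bad"]] <- list(id = "bad", stoich = c(X = 1),
                               dG0_prime = 0, slp_atp = 0,
                               cpt_capable = FALSE, flux = 1)
  expect_error(overall_stoichiometry(v), "close")
})

test_that("carbon atom economy counts gross CO2 consumption", {
  # fixes 3 CO2, releases 1, product keeps 2 carbons -> economy 2/3
  p <- as_pathway(list(
    id = "econ", name = "economy toy", oxygen_class = "anaerobic",
    metabolites = list(
      new_metabolite("CO2", role = "clamped", clamp = 1e-2, carbon = 1),
      new_metabolite("H2", role = "clamped", carbon = 0),
      new_metabolite("X3", carbon = 3),
      new_metabolite("P2", carbon = 2)),
    carriers = list(),
    reactions = list(
      new_reaction("fix", list(CO2 = -3, H2 = -3, X3 = 1), -60),
      new_reaction("rel", list(X3 = -1, P2 = 1, CO2 = 1), -10)),
    end_product = "P2",
    overall = list(stoich = list(CO2 = -2, H2 = -3, P2 = 1),
                   dG0_prime = -70),
    declared = NULL))
  v <- first_variant(p)
  expect_equal(carbon_atom_economy(v), 2 / 3)
})
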