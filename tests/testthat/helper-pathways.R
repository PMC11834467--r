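# Builders for the tiny pathways used across the test files.

# a single-reaction pathway A -> B with clamped endpoints
single_reaction_pathway <- function(dG0 = -40, cpt = FALSE, slp = 0,
                                    clamp = 1e-3) {
  as_pathway(list(
    id = "single", name = "single reaction", oxygen_class = "anaerobic",
    metabolites = list(
      new_metabolite("A", role = "clamped", clamp = clamp, carbon = 1),
      new_metabolite("B", role = "clamped", clamp = clamp, carbon = 1)),
    carriers = list(),
    reactions = list(new_reaction("R1", list(A = -1, B = 1), dG0,
                                  slp_atp = slp, cpt_capable = cpt)),
    end_product = "B",
    overall = list(stoich = list(A = -1, B = 1), dG0_prime = dG0),
    declared = NULL))
}

# the worked 3-step chain: total dissipation 30 kJ/mol, one optional CPT site
chain3 <- function(cpt_site = integer(0)) {
  synthetic_spec(n_reactions = 3, total_dG0 = -30, cpt_sites = cpt_site)
}

first_variant <- function(pathway) enumerate_variants(pathway)[[1]]

# seeded random oracle-sized instance: a chain small enough for
# brute_force_oracle, possibly with one redox step and CPT sites
random_oracle_instance <- function(seed) {
  set.seed(seed)
  n <- sample(2:4, 1)
  with_redox <- runif(1) < 0.4 && n <= 3
  spec <- synthetic_spec(
    n_reactions = n,
    total_dG0 = -runif(1, 10, 60),
    split = "random",
    cpt_sites = sample(seq_len(n), sample(0:min(2, n), 1)),
    redox_steps = if (with_redox) sample(seq_len(n), 1) else integer(0),
    carrier_sets = if (with_redox) list("NAD") else list(),
    slp_steps = if (runif(1) < 0.3)
      stats::setNames(sample(c(-1, 1), 1), sample(seq_len(n), 1)) else
      numeric(0),
    clamp_sub = 10^runif(1, -5, -3),
    clamp_prod = 10^runif(1, -5, -3),
    seed = seed)
  generate_pathway(spec)
}

# driving forces of every reaction at an optimization witness
witness_forces <- function(sys, res) {
  F <- sys$rhs0 - as.vector(sys$S %*% res$ln_conc)
  F[sys$cpt_idx] <- F[sys$cpt_idx] - sys$pmf_rt * res$n_p[sys$cpt_idx]
  stats::setNames(F, sys$reaction_ids)
}
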