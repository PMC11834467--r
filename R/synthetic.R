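# Synthetic pathways with known ground truth.
#
# A synthetic pathway is a chain (or cycle) of carbon-neutral conversions
# M0 -> M1 -> ... -> Mn with clamped endpoints, a prescribed total standard
# dissipation, and optional CPT sites, redox steps (written against H2) and
# SLP steps.  For chains with equal dG0 split and slack concentration
# bounds the max-min driving force has the closed form implemented in
# analytic_mdf(), which makes every optimizer stage testable end to end.

#' Specification of a synthetic pathway
#'
#' @param n_reactions number of elementary steps.
#' @param topology `"chain"` or `"cycle"` (a cycle closes the last step back
#'   onto the first intermediate while consuming a clamped substrate).
#' @param total_dG0 summed standard Gibbs energy of the steps, kJ/mol
#'   (negative = exergonic).
#' @param split `"equal"` or `"random"` (symmetric Dirichlet over the total).
#' @param cpt_sites integer positions of CPT-capable steps.
#' @param redox_steps integer positions of redox steps (each consumes one H2
#'   and chooses among `carrier_sets[[i]]` carriers).
#' @param carrier_sets list (parallel to `redox_steps`) of carrier id sets;
#'   carriers are drawn from a small built-in table.
#' @param slp_steps named numeric: position -> slp_atp of that step.
#' @param clamp_sub,clamp_prod clamped endpoint concentrations, mol/L.
#' @param seed integer seed controlling the random split.
#' @return an object of class `pmdf_synth_spec`.
#' @export
synthetic_spec <- function(n_reactions = 3, topology = c("chain", "cycle"),
                           total_dG0 = -30, split = c("equal", "random"),
                           cpt_sites = integer(0), redox_steps = integer(0),
                           carrier_sets = list(), slp_steps = numeric(0),
                           clamp_sub = 1e-3, clamp_prod = 1e-3, seed = 1L) {
  topology <- match.arg(topology)
  split <- match.arg(split)
  stopifnot(n_reactions >= 1,
            all(cpt_sites >= 1), all(cpt_sites <= n_reactions),
            all(redox_steps >= 1), all(redox_steps <= n_reactions),
            length(carrier_sets) == length(redox_steps))
  if (length(slp_steps)) {
    pos <- as.integer(names(slp_steps))
    stopifnot(!anyNA(pos), all(pos >= 1), all(pos <= n_reactions))
  }
  spec <- list(n_reactions = as.integer(n_reactions), topology = topology,
               total_dG0 = total_dG0, split = split,
               cpt_sites = as.integer(cpt_sites),
               redox_steps = as.integer(redox_steps),
               carrier_sets = carrier_sets, slp_steps = slp_steps,
               clamp_sub = clamp_sub, clamp_prod = clamp_prod,
               seed = as.integer(seed))
  class(spec) <- "pmdf_synth_spec"
  spec
}

# built-in carrier table for synthetic pathways (standard literature values)
synthetic_carriers <- function(ids) {
  tab <- list(
    NAD = new_carrier("NAD", -0.320), NADP = new_carrier("NADP", -0.380),
    FAD = new_carrier("FAD", -0.220), Fd = new_carrier("Fd", -0.430),
    quinone = new_carrier("quinone", 0.090), F420 = new_carrier("F420", -0.360))
  unknown <- setdiff(ids, names(tab))
  if (length(unknown)) {
    stop("unknown synthetic carriers: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tab[ids]
}

#' Generate a synthetic pathway from a specification
#'
#' Deterministic per seed; the result passes all pathway invariants.
#'
#' @param spec a `pmdf_synth_spec`.
#' @return a `pmdf_pathway`.
#' @export
generate_pathway <- function(spec) {
  stopifnot(inherits(spec, "pmdf_synth_spec"))
  n <- spec$n_reactions
  if (spec$split == "equal") {
    dg <- rep(spec$total_dG0 / n, n)
  } else {
    rng <- local({
      set.seed(spec$seed)
      g <- stats::rgamma(n, shape = 1)
      g / sum(g)
    })
    dg <- spec$total_dG0 * rng
  }
  met_ids <- paste0("M", 0:n)
  mets <- lapply(seq_along(met_ids), function(i) {
    id <- met_ids[i]
    if (i == 1) {
      new_metabolite(id, role = "clamped", clamp = spec$clamp_sub, carbon = 1)
    } else if (i == length(met_ids) && spec$topology == "chain") {
      new_metabolite(id, role = "clamped", clamp = spec$clamp_prod, carbon = 1)
    } else {
      new_metabolite(id, role = "internal", carbon = 1)
    }
  })
  mets <- c(mets, list(
    new_metabolite("H2", role = "clamped", carbon = 0),
    new_metabolite("H2O", role = "fixed_activity", carbon = 0)))
  carrier_ids <- unique(unlist(spec$carrier_sets))
  carriers <- synthetic_carriers(carrier_ids)
  reactions <- vector("list", n)
  for (i in seq_len(n)) {
    from <- met_ids[i]
    to <- if (i == n && spec$topology == "cycle") met_ids[2] else met_ids[i + 1]
    st <- list(-1, 1); names(st) <- c(from, to)
    if (from == to) stop("degenerate cycle step", call. = FALSE)
    redox <- NULL
    if (i %in% spec$redox_steps) {
      st[["H2"]] <- -1
      which_set <- match(i, spec$redox_steps)
      redox <- list(n_e = 2L, carriers = spec$carrier_sets[[which_set]],
                    direction = "reduction")
    }
    slp <- if (as.character(i) %in% names(spec$slp_steps))
      spec$slp_steps[[as.character(i)]] else 0
    reactions[[i]] <- new_reaction(
      id = sprintf("R%02d", i), stoich = st, dG0_prime = dg[i],
      slp_atp = slp, cpt_capable = i %in% spec$cpt_sites, redox = redox)
  }
  overall <- local({
    net <- numeric(0)
    for (r in reactions) for (sp in names(r$stoich)) {
      net[sp] <- (if (sp %in% names(net)) net[[sp]] else 0) + r$stoich[[sp]]
    }
    list(stoich = as.list(net[abs(net) > 1e-9]),
         dG0_prime = sum(dg))
  })
  end_product <- if (spec$topology == "chain") met_ids[n + 1] else met_ids[2]
  as_pathway(list(
    id = sprintf("synthetic_%s_n%d_seed%d", spec$topology, n, spec$seed),
    name = "synthetic pathway", oxygen_class = "anaerobic",
    metabolites = mets, carriers = carriers, reactions = reactions,
    end_product = end_product, overall = overall,
    declared = NULL))
}

#' Closed-form MDF of an equal-split synthetic chain
#'
#' For a chain with equal standard-energy split and slack concentration
#' bounds, the optimum spreads the total dissipation evenly:
#' `MDF = (-total_dG0 + RT ln(clamp terms) - pmf * sum(n_p) - dG_ATP * netSLP)
#' / n_reactions`, where the clamp term covers the clamped endpoints and any
#' H2 consumed by redox steps.
#'
#' @param spec a `pmdf_synth_spec` with `topology = "chain"`,
#'   `split = "equal"`.
#' @param env environmental conditions.
#' @param total_np flux-weighted CPT total assumed recovered.
#' @return MDF in kJ/mol.
#' @export
analytic_mdf <- function(spec, env = env_conditions(), total_np = 0) {
  stopifnot(inherits(spec, "pmdf_synth_spec"))
  if (spec$topology != "chain" || spec$split != "equal") {
    stop("analytic MDF is defined for equal-split chains only", call. = FALSE)
  }
  RT <- rt_kj(env$temperature)
  net_slp <- sum(spec$slp_steps)          # ATP formed (+) / consumed (-)
  n_h2 <- length(spec$redox_steps)
  D <- -spec$total_dG0 +
    RT * (log(spec$clamp_sub) - log(spec$clamp_prod) +
            n_h2 * log(env$conc_H2)) -
    env$pmf_per_proton * total_np - env$dG_ATP * net_slp
  D / spec$n_reactions
}
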