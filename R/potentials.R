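# Electron-carrier potential analysis.
#
# Redox steps are rewritten as half-reactions with no named carrier: the
# electrons of step j are a pseudo-species whose "log-activity" is the
# dimensionless potential Phi_j = -F E_j / RT, a continuous decision
# variable.  A generic donor half-reaction (H2 -> 2H+ + 2e-, or its reverse
# for oxidation steps) closes each electron balance against the terminal
# donor.  After the usual two-stage optimization, the set of per-step
# potentials compatible with the optimal ATP cost and MDF is an interval,
# found by fixing the integer optimum and the optimal MDF and then
# maximizing and minimizing each Phi_j as a plain LP.

# standard Gibbs energy of H2 -> 2H+ + 2e- with electrons at Phi = 0 (E = 0)
dG0_donor_half <- function() 2 * FARADAY * E0_H2_COUPLE

#' Build the carrier-free potential system of a pathway
#'
#' @param pathway a `pmdf_pathway` with at least one redox step.
#' @param env environmental conditions.
#' @param E_bounds allowed reduction-potential window in volts for every
#'   electron, default `c(-0.6, 0.4)` (covers all biological carriers).
#' @return a `pmdf_system` whose variables include one dimensionless
#'   potential per redox step (fields `phi_vars`, `phi_reactions`).
#' @export
build_potential_system <- function(pathway, env = env_conditions(),
                                   E_bounds = c(-0.6, 0.4)) {
  stopifnot(inherits(pathway, "pmdf_pathway"))
  redox_ids <- names(which(vapply(pathway$reactions,
                                  function(r) !is.null(r$redox), TRUE)))
  if (!length(redox_ids)) {
    stop("pathway has no redox steps; nothing to analyze", call. = FALSE)
  }
  # Phi = -FE/RT decreases in E, so the E window maps to reversed Phi bounds
  phi_bounds <- sort(nernst_phi(E_bounds, env$temperature))
  mets <- pathway$metabolites
  reactions <- list()
  phi_vars <- character(0)
  for (r in pathway$reactions) {
    if (is.null(r$redox)) {
      reactions[[r$id]] <- r
      next
    }
    ne <- r$redox$n_e
    h <- if (r$redox$direction == "reduction") -(ne / 2) else (ne / 2)
    e_id <- paste0("e_", r$id)
    mets[[e_id]] <- new_metabolite(e_id, paste("electrons of", r$id),
                                   carbon = 0, role = "internal",
                                   bounds = phi_bounds)
    st <- r$stoich
    h2 <- if ("H2" %in% names(st)) st[["H2"]] else 0
    st[["H2"]] <- h2 - h              # drop the hydrogen written in the file
    st[[e_id]] <- h * ne / abs(h)     # -ne for reductions, +ne for oxidations
    r2 <- r
    r2$stoich <- st[abs(st) > 1e-12]
    r2$dG0_prime <- r$dG0_prime + h * dG0_donor_half()
    reactions[[r$id]] <- r2
    # generic donor half-reaction for this step's electrons
    dn <- if (h < 0) {
      list(stoich = c(H2 = -abs(h), setNames(ne, e_id)),
           dG0 = abs(h) * dG0_donor_half())
    } else {
      list(stoich = c(H2 = abs(h), setNames(-ne, e_id)),
           dG0 = -abs(h) * dG0_donor_half())
    }
    reactions[[paste0("donor_", r$id)]] <- list(
      id = paste0("donor_", r$id), stoich = dn$stoich, dG0_prime = dn$dG0,
      slp_atp = 0, cpt_capable = FALSE, redox = NULL, flux = r$flux,
      is_regen = TRUE)
    phi_vars <- c(phi_vars, setNames(e_id, r$id))
  }
  v <- list(pathway_id = pathway$id, pathway_name = pathway$name,
            carrier_assignment = character(0), metabolites = mets,
            carriers = pathway$carriers, reactions = reactions,
            end_product = pathway$end_product, overall = pathway$overall,
            ratio_constraints = list())
  class(v) <- "pmdf_variant"
  sys <- build_system(v, env)
  sys$phi_vars <- phi_vars
  sys$phi_reactions <- redox_ids
  sys
}

#' Enumerate all integer optima of a two-stage solution
#'
#' Lists every integer translocation assignment that attains both the
#' stage-1 optimal CPT total and the stage-2 optimal MDF (the solution
#' pool).  Assignments over the CPT sites are enumerated exhaustively and
#' kept when their continuous relaxation reaches the optimal MDF.
#'
#' @param system a `pmdf_system` (plain or potential).
#' @param epsilon translocations traded, as in [maximize_mdf()].
#' @param imposed_mdf driving-force floor, kJ/mol.
#' @param tol MDF equality tolerance (dimensionless, on B).
#' @return list with `n_opt`, `mdf_kJ_mol` and `pool` (a list of named
#'   integer vectors over the CPT-capable reactions).
#' @export
enumerate_optimal_pool <- function(system, epsilon = 0, imposed_mdf = 0,
                                   tol = 1e-6) {
  s1 <- maximize_cpt(system, imposed_mdf = imposed_mdf)
  if (s1$status != "optimal") stop("system infeasible", call. = FALSE)
  s2 <- maximize_mdf(system, n_opt = s1$total_cpt, epsilon = epsilon,
                     imposed_mdf = imposed_mdf)
  if (s2$status != "optimal") stop("no stage-2 optimum", call. = FALSE)
  k <- length(system$cpt_idx)
  target <- s1$total_cpt - epsilon
  if (k == 0) {
    return(list(n_opt = 0, mdf_kJ_mol = s2$mdf_kJ_mol, pool = list(numeric(0))))
  }
  cap <- system$cpt_cap
  combos <- as.matrix(do.call(expand.grid, rep(list(-cap:cap), k)))
  fw <- system$flux[system$cpt_idx]
  combos <- combos[abs(combos %*% fw - target) < 1e-9, , drop = FALSE]
  B_opt <- s2$mdf_kJ_mol / system$RT
  pool <- list()
  for (i in seq_len(nrow(combos))) {
    lp <- assemble_lp(system, with_B = TRUE, fmin = max(0, imposed_mdf / system$RT),
                      np_fix = combos[i, ])
    sol <- lp_box(c(rep(0, lp$n - 1), 1), lp$mat, lp$dir, lp$rhs,
                  lp$lower, lp$upper)
    if (sol$status == "optimal" && sol$objective >= B_opt - tol) {
      np <- setNames(combos[i, ], system$reaction_ids[system$cpt_idx])
      pool[[length(pool) + 1L]] <- np
    }
  }
  list(n_opt = s1$total_cpt, mdf_kJ_mol = s2$mdf_kJ_mol, pool = pool)
}

#' Optimal potential range of one redox step
#'
#' For every pool member the integer translocations are fixed, every
#' driving force is held at or above the optimal MDF, and the step's
#' dimensionless potential is maximized and minimized as a pure LP; the
#' reported range is the union over the pool, converted to volts.
#'
#' @param system a potential system from [build_potential_system()].
#' @param pool result of [enumerate_optimal_pool()].
#' @param reaction_id id of a redox step.
#' @return list with `reaction`, `E_min_V`, `E_max_V`, `phi_min`,
#'   `phi_max`, `mdf_kJ_mol`.
#' @export
phi_range <- function(system, pool, reaction_id) {
  if (!reaction_id %in% system$phi_reactions) {
    stop(reaction_id, " is not a redox step of this system", call. = FALSE)
  }
  e_id <- system$phi_vars[[reaction_id]]
  col <- match(e_id, system$var_ids)
  B_opt <- pool$mdf_kJ_mol / system$RT
  phi_lo <- Inf; phi_hi <- -Inf
  for (np in pool$pool) {
    lp <- assemble_lp(system, with_B = TRUE, fmin = 0, np_fix = np)
    lo <- lp$lower; lo[lp$n] <- B_opt - 1e-9  # hold MDF at its optimum
    obj <- numeric(lp$n); obj[col] <- 1
    up <- lp_box(obj, lp$mat, lp$dir, lp$rhs, lo, lp$upper, maximize = TRUE)
    dn <- lp_box(obj, lp$mat, lp$dir, lp$rhs, lo, lp$upper, maximize = FALSE)
    if (up$status == "optimal") phi_hi <- max(phi_hi, up$objective)
    if (dn$status == "optimal") phi_lo <- min(phi_lo, dn$objective)
  }
  if (!is.finite(phi_hi) || !is.finite(phi_lo)) {
    stop("no feasible potential for ", reaction_id, call. = FALSE)
  }
  list(reaction = reaction_id,
       E_min_V = phi_to_volts(phi_hi, system$env$temperature),
       E_max_V = phi_to_volts(phi_lo, system$env$temperature),
       phi_min = phi_lo, phi_max = phi_hi,
       mdf_kJ_mol = pool$mdf_kJ_mol)
}

#' Optimal carrier potential ranges across an electron-donor scan
#'
#' For each hydrogen concentration, the pathway is optimized carrier-free
#' (ATP yield first, then MDF), the integer solution pool is enumerated and
#' the optimal potential range of every redox step is computed.
#'
#' @param pathway a `pmdf_pathway` with redox steps.
#' @param env base environmental conditions (CO2, temperature etc.).
#' @param log10_h2 vector of log10 hydrogen concentrations (mol/L).
#' @param epsilon translocations traded.
#' @param E_bounds potential window in volts.
#' @return data.frame with columns `reaction_id`, `log10_h2`, `E_min_V`,
#'   `E_max_V`, `atp_cost_per_CO2`, `mdf_kJ_mol`; infeasible grid points are
#'   absent (gaps).
#' @export
carrier_range_scan <- function(pathway, env = env_conditions(),
                               log10_h2 = seq(-6, -1, by = 0.5),
                               epsilon = 0, E_bounds = c(-0.6, 0.4)) {
  rows <- list()
  for (lh in log10_h2) {
    envi <- env
    envi$conc_H2 <- 10^lh
    sys <- build_potential_system(pathway, envi, E_bounds = E_bounds)
    pool <- tryCatch(enumerate_optimal_pool(sys, epsilon = epsilon),
                     error = function(e) NULL)
    if (is.null(pool) || !length(pool$pool)) next
    np1 <- pool$pool[[1]]
    atp <- local({
      slp_cost <- -sum(sys$flux * sys$slp)
      total_cpt <- pool$n_opt - epsilon
      net <- overall_stoichiometry(sys$variant)
      co2 <- -net$stoich[["CO2"]]
      (slp_cost - total_cpt / envi$r_H_per_ATP) / co2
    })
    for (rid in sys$phi_reactions) {
      pr <- phi_range(sys, pool, rid)
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = rid, log10_h2 = lh,
        E_min_V = pr$E_min_V, E_max_V = pr$E_max_V,
        atp_cost_per_CO2 = atp, mdf_kJ_mol = pool$mdf_kJ_mol,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Match known electron carriers against an optimal potential range
#'
#' A carrier is compatible when its Nernst potential
#' `E0' - (RT/nF) ln([EC_red]/[EC_ox])` falls inside `[E_min, E_max]` for
#' some admissible red/ox ratio; the compatible ratio sub-interval is
#' returned.
#'
#' @param range a potential range (list with `E_min_V`, `E_max_V`).
#' @param carriers list of carrier records (`id`, `E0_prime_V`, `electrons`,
#'   `ratio_bounds`), e.g. `pathway$carriers`.
#' @param temperature kelvin.
#' @return data.frame with one row per carrier: `carrier`, `compatible`,
#'   `ratio_lo`, `ratio_hi` (NA when incompatible).
#' @export
match_known_carriers <- function(range, carriers, temperature = 298.15) {
  RT <- rt_kj(temperature)
  rows <- lapply(carriers, function(cc) {
    nF <- cc$electrons * FARADAY
    # E(r) is decreasing in r: ratio achieving a potential E
    r_of <- function(E) exp(nF * (cc$E0_prime_V - E) / RT)
    r_lo <- max(r_of(range$E_max_V), cc$ratio_bounds[1])
    r_hi <- min(r_of(range$E_min_V), cc$ratio_bounds[2])
    ok <- r_lo <= r_hi * (1 + 1e-12)
    data.frame(carrier = cc$id, compatible = ok,
               ratio_lo = if (ok) r_lo else NA_real_,
               ratio_hi = if (ok) r_hi else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
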