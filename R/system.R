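# Energy constraint system for one pathway variant.
#
# For reaction j with SLP-adjusted equilibrium constant K_j, the feasibility
# (driving-force) constraint in natural-log space is
#
#     S'_j . lnC  +  (pmf/RT) n_p,j  +  F_j  <=  ln K_j  - (clamped terms)
#
# with F_j >= 0 the dimensionless driving force, n_p,j the integer protons
# translocated at CPT-capable steps, and lnC the internal metabolite
# log-concentrations bounded by the environment.  Clamped species (CO2, H2)
# and fixed-activity species (water, H+) are folded into the constant.

#' Build the energy constraint system of a variant
#'
#' @param variant a `pmdf_variant` from [make_variant()] or
#'   [enumerate_variants()].
#' @param env environmental conditions from [env_conditions()].
#' @return an object of class `pmdf_system` with the stoichiometric matrix
#'   over variable metabolites, per-reaction right-hand sides, CPT site
#'   indices and carrier-ratio constraints.
#' @export
build_system <- function(variant, env = env_conditions()) {
  stopifnot(inherits(variant, "pmdf_variant"), inherits(env, "pmdf_env"))
  RT <- rt_kj(env$temperature)
  mets <- variant$metabolites
  species <- unique(unlist(lapply(variant$reactions,
                                  function(r) names(r$stoich))))
  unknown <- setdiff(species, names(mets))
  if (length(unknown)) {
    stop("reactions reference unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  clamp_of <- function(m) {
    if (m$id == "CO2") return(env$conc_CO2)
    if (m$id == "H2") return(env$conc_H2)
    if (!is.null(m$clamp)) return(m$clamp)
    stop("clamped metabolite ", m$id, " has no clamp value", call. = FALSE)
  }
  roles <- vapply(mets[species], `[[`, "", "role")
  var_ids <- species[roles == "internal"]
  lnclamp <- vapply(species, function(sp) {
    m <- mets[[sp]]
    switch(m$role, internal = 0, fixed_activity = 0, clamped = log(clamp_of(m)))
  }, 0)

  nr <- length(variant$reactions)
  nv <- length(var_ids)
  S <- matrix(0, nr, nv, dimnames = list(names(variant$reactions), var_ids))
  rhs0 <- numeric(nr)
  for (i in seq_len(nr)) {
    r <- variant$reactions[[i]]
    lnK <- ln_equilibrium_constant(r, env)
    const <- 0
    for (sp in names(r$stoich)) {
      if (mets[[sp]]$role == "internal") {
        S[i, sp] <- S[i, sp] + r$stoich[[sp]]
      } else {
        const <- const + r$stoich[[sp]] * lnclamp[[sp]]
      }
    }
    rhs0[i] <- lnK - const
  }
  cpt_idx <- which(vapply(variant$reactions, function(r)
    isTRUE(r$cpt_capable), TRUE))
  ratio <- list()
  for (rc in variant$ratio_constraints) {
    if (rc$red %in% var_ids && rc$ox %in% var_ids) {
      ratio[[length(ratio) + 1L]] <- list(
        red = match(rc$red, var_ids), ox = match(rc$ox, var_ids),
        lo = log(rc$ratio_bounds[1]), hi = log(rc$ratio_bounds[2]))
    }
  }
  sys <- list(
    variant = variant, env = env, RT = RT,
    pmf_rt = env$pmf_per_proton / RT,
    var_ids = var_ids, S = S, rhs0 = rhs0,
    flux = vapply(variant$reactions, `[[`, 0, "flux"),
    slp = vapply(variant$reactions, `[[`, 0, "slp_atp"),
    reaction_ids = names(variant$reactions),
    cpt_idx = cpt_idx, cpt_cap = env$cpt_cap,
    ratio = ratio,
    lnc_lower = vapply(var_ids, function(sp) {
      b <- mets[[sp]]$bounds
      if (is.null(b)) log(env$conc_bounds[1]) else b[1]
    }, 0),
    lnc_upper = vapply(var_ids, function(sp) {
      b <- mets[[sp]]$bounds
      if (is.null(b)) log(env$conc_bounds[2]) else b[2]
    }, 0)
  )
  class(sys) <- "pmdf_system"
  sys
}

#' @export
print.pmdf_system <- function(x, ...) {
  cat(sprintf("<pmdf_system> %d reactions, %d variable metabolites, %d CPT sites\n",
              nrow(x$S), ncol(x$S), length(x$cpt_idx)))
  invisible(x)
}

# --- shared LP assembly -----------------------------------------------------

# Rows of the LP over decision vector [lnC (nv), n_p (k), (B)]:
#   reaction rows, carrier-ratio rows.  `fmin` is the fixed driving-force
#   floor used when B is absent (stage 1).
assemble_lp <- function(sys, with_B, fmin = 0, np_fix = NULL) {
  nv <- ncol(sys$S)
  k <- length(sys$cpt_idx)
  nB <- as.integer(with_B)
  n <- nv + k + nB
  nr <- nrow(sys$S)
  mat <- matrix(0, nr, n)
  mat[, seq_len(nv)] <- sys$S
  if (k) {
    for (jj in seq_len(k)) mat[sys$cpt_idx[jj], nv + jj] <- sys$pmf_rt
  }
  if (nB) mat[, n] <- 1
  dir <- rep("<=", nr)
  rhs <- sys$rhs0 - if (nB) 0 else fmin
  for (rc in sys$ratio) {
    row <- numeric(n)
    row[rc$red] <- 1; row[rc$ox] <- -1
    mat <- rbind(mat, row, -row)
    dir <- c(dir, "<=", "<=")
    rhs <- c(rhs, rc$hi, -rc$lo)
  }
  lower <- c(sys$lnc_lower, rep(-sys$cpt_cap, k), if (nB) fmin)
  upper <- c(sys$lnc_upper, rep(sys$cpt_cap, k), if (nB) 1e4)
  if (!is.null(np_fix)) {
    stopifnot(length(np_fix) == k)
    lower[nv + seq_len(k)] <- np_fix
    upper[nv + seq_len(k)] <- np_fix
  }
  list(mat = mat, dir = dir, rhs = rhs, lower = lower, upper = upper,
       nv = nv, k = k, nB = nB, n = n)
}

np_full <- function(sys, np_sites) {
  np <- setNames(rep(0, length(sys$reaction_ids)), sys$reaction_ids)
  if (length(sys$cpt_idx)) np[sys$cpt_idx] <- np_sites
  np
}

# Assemble an OptimizationResult
make_result <- function(sys, status, np_sites = NULL, ln_conc = NULL,
                        mdf = NA_real_, epsilon = 0, imposed_mdf = 0) {
  res <- list(status = status, epsilon = epsilon, imposed_mdf = imposed_mdf)
  if (status == "optimal") {
    np <- np_full(sys, np_sites)
    total_cpt <- sum(sys$flux * np)
    slp_cost <- -sum(sys$flux * sys$slp)
    net <- overall_stoichiometry(sys$variant)
    co2 <- if ("CO2" %in% names(net$stoich)) -net$stoich[["CO2"]] else 0
    atp_product <- slp_cost - total_cpt / sys$env$r_H_per_ATP
    res$n_p <- np
    res$total_cpt <- total_cpt
    res$mdf_kJ_mol <- mdf
    res$ln_conc <- setNames(ln_conc, sys$var_ids)
    res$atp_cost_per_product <- atp_product
    res$co2_fixed_per_product <- co2
    res$atp_cost_per_CO2 <- if (co2 > 0) atp_product / co2 else NA_real_
  }
  class(res) <- "pmdf_result"
  res
}

#' @export
print.pmdf_result <- function(x, ...) {
  cat(sprintf("<pmdf_result> status: %s\n", x$status))
  if (x$status == "optimal") {
    cat(sprintf("  total CPT %g, MDF %.4f kJ/mol, ATP cost %.4f /CO2 (%.4f /product)\n",
                x$total_cpt, x$mdf_kJ_mol, x$atp_cost_per_CO2,
                x$atp_cost_per_product))
  }
  invisible(x)
}
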