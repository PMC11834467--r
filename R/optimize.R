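# Two-stage optimization of a pathway variant (epsilon-constraint method).
#
# Stage 1 fixes all driving-force terms at a floor (zero, or an imposed MDF)
# and maximizes the flux-weighted sum of chemiosmotic proton translocations;
# stage 2 constrains that sum to the stage-1 optimum minus epsilon traded
# translocations and maximizes B, the smallest driving force of any step.

#' Stage 1: maximize chemiosmotic proton recovery
#'
#' @param system a `pmdf_system` from [build_system()].
#' @param imposed_mdf driving-force floor in kJ/mol applied to every step
#'   (0 = thermodynamic feasibility only).
#' @return a `pmdf_result`; status `"infeasible"` when no concentration
#'   assignment satisfies all constraints.
#' @export
maximize_cpt <- function(system, imposed_mdf = 0) {
  stopifnot(imposed_mdf >= 0)
  lp <- assemble_lp(system, with_B = FALSE, fmin = imposed_mdf / system$RT)
  k <- lp$k
  obj <- c(rep(0, lp$nv), if (k) system$flux[system$cpt_idx])
  sol <- milp_box(obj, lp$mat, lp$dir, lp$rhs, lp$lower, lp$upper,
                  int_idx = if (k) lp$nv + seq_len(k) else integer(0))
  if (sol$status != "optimal") {
    return(make_result(system, sol$status, imposed_mdf = imposed_mdf))
  }
  np <- if (k) round(sol$x[lp$nv + seq_len(k)]) else numeric(0)
  make_result(system, "optimal", np_sites = np,
              ln_conc = sol$x[seq_len(lp$nv)], mdf = imposed_mdf,
              imposed_mdf = imposed_mdf)
}

#' Stage 2: maximize the minimum driving force at fixed proton recovery
#'
#' Adds the equality `sum(flux * n_p) = n_opt - epsilon` and maximizes B,
#' the smallest dimensionless driving force; reported as `B * RT` in kJ/mol.
#'
#' @param system a `pmdf_system`.
#' @param n_opt stage-1 optimal flux-weighted CPT total.
#' @param epsilon number of proton translocations traded for driving force.
#' @param imposed_mdf lower bound on the MDF in kJ/mol.
#' @param canonical if `TRUE`, break ties among equally optimal integer
#'   assignments by lexicographically minimizing the `n_p` vector in
#'   reaction order.
#' @return a `pmdf_result`; an unreachable target is reported as status
#'   `"infeasible"`, not an error.
#' @export
maximize_mdf <- function(system, n_opt, epsilon = 0, imposed_mdf = 0,
                         canonical = FALSE) {
  stopifnot(epsilon >= 0)
  lp <- assemble_lp(system, with_B = TRUE, fmin = imposed_mdf / system$RT)
  k <- lp$k
  target <- n_opt - epsilon
  mat <- lp$mat; dir <- lp$dir; rhs <- lp$rhs
  if (k) {
    row <- numeric(lp$n)
    row[lp$nv + seq_len(k)] <- system$flux[system$cpt_idx]
    mat <- rbind(mat, row); dir <- c(dir, "=="); rhs <- c(rhs, target)
  } else if (abs(target) > 1e-9) {
    return(make_result(system, "infeasible", epsilon = epsilon,
                       imposed_mdf = imposed_mdf))
  }
  obj <- c(rep(0, lp$n - 1), 1)
  int_idx <- if (k) lp$nv + seq_len(k) else integer(0)
  sol <- milp_box(obj, mat, dir, rhs, lp$lower, lp$upper, int_idx = int_idx)
  if (sol$status != "optimal") {
    return(make_result(system, sol$status, epsilon = epsilon,
                       imposed_mdf = imposed_mdf))
  }
  B <- sol$x[lp$n]
  np <- if (k) round(sol$x[lp$nv + seq_len(k)]) else numeric(0)
  lnc <- sol$x[seq_len(lp$nv)]
  if (canonical && k > 1) {
    # fix B at its optimum and lexicographically minimize n_p
    lo <- lp$lower; up <- lp$upper
    lo[lp$n] <- B - 1e-7
    for (jj in seq_len(k)) {
      ej <- numeric(lp$n); ej[lp$nv + jj] <- 1
      s2 <- milp_box(ej, mat, dir, rhs, lo, up, int_idx = int_idx,
                     maximize = FALSE)
      if (s2$status != "optimal") break
      val <- round(s2$x[lp$nv + jj])
      lo[lp$nv + jj] <- val; up[lp$nv + jj] <- val
      np[jj] <- val
      lnc <- s2$x[seq_len(lp$nv)]
    }
  }
  make_result(system, "optimal", np_sites = np, ln_conc = lnc,
              mdf = B * system$RT, epsilon = epsilon,
              imposed_mdf = imposed_mdf)
}

#' Optimize a variant: ATP yield first, then max-min driving force
#'
#' Runs stage 1 ([maximize_cpt()]) and stage 2 ([maximize_mdf()]) with
#' `epsilon` translocations traded.  The reported net ATP cost per CO2 fixed
#' is `(SLP consumed - SLP produced - total_cpt / r_H_per_ATP)` divided by
#' the moles of CO2 fixed per mole of product.
#'
#' @inheritParams maximize_mdf
#' @param variant a `pmdf_variant`.
#' @param env environmental conditions.
#' @return a `pmdf_result`.
#' @export
optimize_variant <- function(variant, env = env_conditions(), epsilon = 0,
                             imposed_mdf = 0, canonical = FALSE) {
  sys <- build_system(variant, env)
  s1 <- maximize_cpt(sys, imposed_mdf = imposed_mdf)
  if (s1$status != "optimal") return(s1)
  maximize_mdf(sys, n_opt = s1$total_cpt, epsilon = epsilon,
               imposed_mdf = imposed_mdf, canonical = canonical)
}

#' Best variant of a pathway under given conditions
#'
#' Optimizes every carrier-assignment variant and returns the winner:
#' objective `"atp"` minimizes net ATP cost per CO2 (ties broken by larger
#' MDF, then by the lexicographically first carrier assignment, which is the
#' enumeration order); `"mdf"` maximizes MDF (ties by lower ATP cost).
#'
#' @inheritParams optimize_variant
#' @param pathway a `pmdf_pathway`.
#' @param objective `"atp"` or `"mdf"`.
#' @return `list(variant =, result =, index =)`; result status
#'   `"infeasible"` when every variant is infeasible.
#' @export
best_variant <- function(pathway, env = env_conditions(), epsilon = 0,
                         objective = c("atp", "mdf"), imposed_mdf = 0) {
  objective <- match.arg(objective)
  variants <- enumerate_variants(pathway)
  best <- NULL
  for (i in seq_along(variants)) {
    res <- optimize_variant(variants[[i]], env, epsilon = epsilon,
                            imposed_mdf = imposed_mdf)
    if (res$status != "optimal") next
    cost <- if (is.finite(res$atp_cost_per_CO2)) res$atp_cost_per_CO2 else
      res$atp_cost_per_product  # pathways that fix no CO2 (synthetic chains)
    key <- if (objective == "atp") {
      c(cost, -res$mdf_kJ_mol)
    } else {
      c(-res$mdf_kJ_mol, cost)
    }
    if (is.null(best) ||
        key[1] < best$key[1] - 1e-9 ||
        (abs(key[1] - best$key[1]) <= 1e-9 && key[2] < best$key[2] - 1e-9)) {
      best <- list(variant = variants[[i]], result = res, index = i, key = key)
    }
  }
  if (is.null(best)) {
    return(list(variant = NULL,
                result = structure(list(status = "infeasible"),
                                   class = "pmdf_result"),
                index = NA_integer_))
  }
  best$key <- NULL
  best
}
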