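# Brute-force verification oracle for small instances.
#
# Independent of the simplex/branch-and-bound path: integer translocation
# assignments are enumerated exhaustively, and for each assignment the
# max-min driving force over the concentration box is found by multiscale
# grid refinement of the (convex, piecewise-linear) worst-violation
# function  g(x) = max_j (S_j x - rhs_j),  whose minimizer gives
# MDF = -RT * min g.

oracle_min_max <- function(S, rhs, lower, upper, ratio_rows = NULL,
                           levels = 14, pts = 7) {
  nv <- ncol(S)
  if (nv == 0) return(max(-rhs))
  lo <- lower; hi <- upper
  best <- Inf
  bestx <- (lower + upper) / 2
  for (lev in seq_len(levels)) {
    grids <- lapply(seq_len(nv), function(j) seq(lo[j], hi[j], length.out = pts))
    X <- as.matrix(do.call(expand.grid, grids))
    g <- apply(S %*% t(X) - rhs, 2, max)
    if (!is.null(ratio_rows)) {
      for (rr in ratio_rows) {
        d <- X[, rr$red] - X[, rr$ox]
        g[d > rr$hi + 1e-9 | d < rr$lo - 1e-9] <- Inf
      }
    }
    i <- which.min(g)
    if (g[i] < best) { best <- g[i]; bestx <- X[i, ] }
    span <- (hi - lo) * 0.35
    lo <- pmax(lower, bestx - span / 2)
    hi <- pmin(upper, bestx + span / 2)
  }
  best
}

#' Exhaustive-enumeration oracle for the two-stage optimization
#'
#' Verifies [optimize_variant()] on oracle-sized instances by enumerating
#' every integer translocation assignment and refining the continuous
#' max-min driving force by grid search (to about 1e-3 in ln-concentration
#' space).  Refuses instances with more than 6 reactions, 4 variable
#' metabolites or 2 CPT sites.
#'
#' @inheritParams optimize_variant
#' @return a `pmdf_result`-like list with `status`, `total_cpt` and
#'   `mdf_kJ_mol`.
#' @export
brute_force_oracle <- function(variant, env = env_conditions(), epsilon = 0,
                               imposed_mdf = 0) {
  sys <- build_system(variant, env)
  nv <- ncol(sys$S); k <- length(sys$cpt_idx)
  if (nrow(sys$S) > 6 || nv > 4 || k > 2) {
    stop("instance too large for the brute-force oracle", call. = FALSE)
  }
  cap <- sys$cpt_cap
  vals <- -cap:cap
  combos <- if (k) as.matrix(do.call(expand.grid, rep(list(vals), k))) else
    matrix(0, 1, 0)
  fw <- if (k) sys$flux[sys$cpt_idx] else numeric(0)
  mdf_of <- function(np) {
    rhs <- sys$rhs0
    if (k) rhs[sys$cpt_idx] <- rhs[sys$cpt_idx] - sys$pmf_rt * np
    g <- oracle_min_max(sys$S, rhs, sys$lnc_lower, sys$lnc_upper, sys$ratio)
    -g * sys$RT
  }
  mdfs <- apply(combos, 1, mdf_of)
  totals <- if (k) as.vector(combos %*% fw) else 0
  feas <- mdfs >= imposed_mdf - 1e-6
  if (!any(feas)) {
    return(structure(list(status = "infeasible", epsilon = epsilon),
                     class = "pmdf_result"))
  }
  n_opt <- max(totals[feas])
  target <- n_opt - epsilon
  sel <- abs(totals - target) < 1e-9   # stage 2: equality, MDF re-maximized
  if (!any(sel)) {
    return(structure(list(status = "infeasible", epsilon = epsilon,
                          n_opt = n_opt), class = "pmdf_result"))
  }
  i <- which(sel)[which.max(mdfs[sel])]
  if (mdfs[i] < max(0, imposed_mdf) - 1e-6) {
    return(structure(list(status = "infeasible", epsilon = epsilon,
                          n_opt = n_opt), class = "pmdf_result"))
  }
  structure(list(status = "optimal", total_cpt = totals[i],
                 n_p_sites = if (k) combos[i, ] else numeric(0),
                 mdf_kJ_mol = mdfs[i], n_opt = n_opt,
                 epsilon = epsilon),
            class = "pmdf_result")
}
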