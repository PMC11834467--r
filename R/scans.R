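# Environmental condition scans: ATP-cost grids over [CO2] x [H2] and
# epsilon-indexed trade-off sweeps over [H2] at fixed [CO2].

#' ATP-cost grid over CO2 and H2 concentrations
#'
#' Optimizes the best variant of a pathway at every grid cell and records
#' the net ATP cost per CO2 fixed, the winning variant and the CPT total.
#' With `imposed_mdf > 0` every reaction must additionally dissipate at
#' least that driving force (the constrained-MDF contour analysis).
#'
#' @param pathway a `pmdf_pathway`.
#' @param log10_co2,log10_h2 grid axes, log10 mol/L.
#' @param imposed_mdf driving-force floor in kJ/mol.
#' @param env base environmental conditions (temperature, pmf, ATP energy).
#' @return data.frame with one row per cell: `log10_co2`, `log10_h2`,
#'   `feasible`, `atp_cost_per_CO2`, `total_cpt`, `mdf_kJ_mol`,
#'   `variant`.  The equivalent donor potential of each `log10_h2` is in
#'   `E_donor_V`.
#' @export
atp_cost_grid <- function(pathway, log10_co2 = seq(-4, -1, by = 0.5),
                          log10_h2 = seq(-6, -1, by = 0.5),
                          imposed_mdf = 0, env = env_conditions()) {
  stopifnot(length(log10_co2) >= 1, length(log10_h2) >= 1)
  rows <- list()
  RT <- rt_kj(env$temperature)
  for (lc in log10_co2) for (lh in log10_h2) {
    envi <- env
    envi$conc_CO2 <- 10^lc
    envi$conc_H2 <- 10^lh
    b <- best_variant(pathway, envi, epsilon = 0, imposed_mdf = imposed_mdf)
    ok <- b$result$status == "optimal"
    rows[[length(rows) + 1L]] <- data.frame(
      log10_co2 = lc, log10_h2 = lh, feasible = ok,
      atp_cost_per_CO2 = if (ok) b$result$atp_cost_per_CO2 else NA_real_,
      total_cpt = if (ok) b$result$total_cpt else NA_real_,
      mdf_kJ_mol = if (ok) b$result$mdf_kJ_mol else NA_real_,
      variant = if (ok) b$index else NA_integer_,
      E_donor_V = E0_H2_COUPLE - RT * log(10^lh) / (2 * FARADAY),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "imposed_mdf") <- imposed_mdf
  out
}

#' Yield/driving-force trade-off sweep over the electron donor
#'
#' For each hydrogen concentration and each number of translocations traded
#' (`epsilons`), optimizes the pathway's best variant and records both the
#' net ATP cost and the MDF, reproducing the sawtooth trade-off curves.
#'
#' @param pathway a `pmdf_pathway`.
#' @param log10_h2 sweep axis, log10 mol/L.
#' @param co2 fixed CO2 concentration, mol/L (default 10 mM).
#' @param epsilons integer vector of translocations traded.
#' @param env base environmental conditions.
#' @return data.frame with columns `log10_h2`, `epsilon`, `feasible`,
#'   `atp_cost_per_CO2`, `mdf_kJ_mol`, `total_cpt`, `variant`.
#' @export
tradeoff_sweep <- function(pathway, log10_h2 = seq(-6, -1, by = 0.25),
                           co2 = 1e-2, epsilons = 0:3,
                           env = env_conditions()) {
  stopifnot(co2 > 0)
  rows <- list()
  for (lh in log10_h2) {
    envi <- env
    envi$conc_CO2 <- co2
    envi$conc_H2 <- 10^lh
    for (eps in epsilons) {
      b <- best_variant(pathway, envi, epsilon = eps)
      ok <- b$result$status == "optimal"
      rows[[length(rows) + 1L]] <- data.frame(
        log10_h2 = lh, epsilon = eps, feasible = ok,
        atp_cost_per_CO2 = if (ok) b$result$atp_cost_per_CO2 else NA_real_,
        mdf_kJ_mol = if (ok) b$result$mdf_kJ_mol else NA_real_,
        total_cpt = if (ok) b$result$total_cpt else NA_real_,
        variant = if (ok) b$index else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
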