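# Scalar thermodynamic primitives shared by all stages.

# Gas constant in kJ/mol/K and Faraday constant in kJ/V/mol.
RGAS <- 8.314462618e-3
FARADAY <- 96.48533212
# Standard transformed potential of the 2H+/H2 couple at pH 7, volts.
E0_H2_COUPLE <- -0.414

#' Gas constant times temperature, kJ/mol
#' @param temperature kelvin.
#' @keywords internal
rt_kj <- function(temperature) RGAS * temperature

#' Flux-force efficacy of a reaction step
#'
#' The fraction of enzyme catalytic capacity realized as net forward flux,
#' `(J+ - J-)/(J+ + J-) = (e^(dG/RT) - 1)/(e^(dG/RT) + 1)`, where `dG_diss`
#' is the Gibbs energy dissipated by the step (the negative of its Gibbs
#' energy change).  Evaluated as `tanh(dG/(2RT))`, which is the same function
#' in a form that is numerically stable for large driving forces.
#'
#' @param dG_diss dissipated Gibbs energy in kJ/mol (positive = forward
#'   driving force).  Vectorized.
#' @param temperature absolute temperature in kelvin.
#' @return dimensionless efficacy in (-1, 1); 0 at equilibrium.
#' @examples
#' flux_force_efficacy(5.45)  # ~0.80
#' @export
flux_force_efficacy <- function(dG_diss, temperature = 298.15) {
  stopifnot(temperature > 0)
  tanh(dG_diss / (2 * rt_kj(temperature)))
}

#' Driving force required for a given flux-force efficacy
#'
#' Inverse of [flux_force_efficacy()].
#'
#' @param ffe efficacy in `[0, 1)`.
#' @inheritParams flux_force_efficacy
#' @return dissipated Gibbs energy in kJ/mol.
#' @examples
#' mdf_for_ffe(0.80)  # ~5.45 kJ/mol
#' @export
mdf_for_ffe <- function(ffe, temperature = 298.15) {
  stopifnot(temperature > 0)
  if (any(ffe < 0) || any(ffe >= 1)) {
    stop("`ffe` must lie in [0, 1)", call. = FALSE)
  }
  2 * rt_kj(temperature) * atanh(ffe)
}

#' Natural log of the (SLP-adjusted) equilibrium constant of a reaction
#'
#' `ln K = -(dG0' + slp_atp * dG_ATP) / RT`: the ATP formed or consumed by
#' substrate-level phosphorylation in the step is folded into the constant,
#' so the energy constraint of the step needs no explicit ATP species.
#'
#' @param reaction a reaction record (list with `dG0_prime` and `slp_atp`),
#'   e.g. an element of `pathway$reactions`.
#' @param env environmental conditions from [env_conditions()].
#' @return dimensionless ln K.
#' @export
ln_equilibrium_constant <- function(reaction, env = env_conditions()) {
  slp <- if (is.null(reaction$slp_atp)) 0 else reaction$slp_atp
  -(reaction$dG0_prime + slp * env$dG_ATP) / rt_kj(env$temperature)
}

#' Dimensionless electrode potential
#'
#' `Phi = -F E / (R T)`, mapping a reduction potential in volts onto the
#' dimensionless scale used by the potential-variable energy constraints.
#'
#' @param E reduction potential in volts. Vectorized.
#' @inheritParams flux_force_efficacy
#' @export
nernst_phi <- function(E, temperature = 298.15) {
  stopifnot(temperature > 0)
  -FARADAY * E / rt_kj(temperature)
}

#' Reduction potential for a dimensionless potential
#' @param phi dimensionless potential.
#' @inheritParams flux_force_efficacy
#' @return volts.
#' @export
phi_to_volts <- function(phi, temperature = 298.15) {
  -phi * rt_kj(temperature) / FARADAY
}

#' Environmental conditions for pathway optimization
#'
#' Bundles the clamped substrate concentrations, temperature and the
#' chemiosmotic bookkeeping parameters.  Defaults: ATP hydrolysis energy
#' 50 kJ/mol and an ATP synthase stoichiometry of 10/3 protons per ATP, so
#' one translocation conserves pmf = 15 kJ/mol and at most
#' `floor(r_H_per_ATP) = 3` protons may be translocated per step in either
#' direction.
#'
#' @param conc_CO2,conc_H2 clamped dissolved concentrations, mol/L.
#' @param temperature kelvin.
#' @param dG_ATP ATP hydrolysis energy backing SLP terms, kJ/mol.
#' @param r_H_per_ATP ATP synthase H+/ATP ratio.
#' @param pmf_per_proton energy of one chemiosmotic proton translocation,
#'   kJ/mol; defaults to `dG_ATP / r_H_per_ATP`.
#' @param conc_bounds permissible concentration range for internal
#'   metabolites, mol/L.
#' @return an object of class `pmdf_env`.
#' @export
env_conditions <- function(conc_CO2 = 1e-2, conc_H2 = 1e-4,
                           temperature = 298.15, dG_ATP = 50,
                           r_H_per_ATP = 10 / 3,
                           pmf_per_proton = dG_ATP / r_H_per_ATP,
                           conc_bounds = c(1e-6, 1e-2)) {
  stopifnot(conc_CO2 > 0, conc_H2 > 0, temperature > 0, dG_ATP > 0,
            r_H_per_ATP >= 1, pmf_per_proton > 0,
            length(conc_bounds) == 2, all(conc_bounds > 0),
            conc_bounds[1] <= conc_bounds[2])
  env <- list(conc_CO2 = conc_CO2, conc_H2 = conc_H2,
              temperature = temperature, dG_ATP = dG_ATP,
              r_H_per_ATP = r_H_per_ATP, pmf_per_proton = pmf_per_proton,
              cpt_cap = max(1L, as.integer(floor(r_H_per_ATP))),
              conc_bounds = conc_bounds)
  class(env) <- "pmdf_env"
  env
}

#' @export
print.pmdf_env <- function(x, ...) {
  cat("Environmental conditions\n")
  cat(sprintf("  [CO2] %g M, [H2] %g M, T %.2f K\n",
              x$conc_CO2, x$conc_H2, x$temperature))
  cat(sprintf("  dG_ATP %.1f kJ/mol, r_H+/ATP %.3f, pmf %.2f kJ/mol, CPT cap %d\n",
              x$dG_ATP, x$r_H_per_ATP, x$pmf_per_proton, x$cpt_cap))
  cat(sprintf("  internal metabolite bounds [%g, %g] M\n",
              x$conc_bounds[1], x$conc_bounds[2]))
  invisible(x)
}
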