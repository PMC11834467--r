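# Pipeline entry point tying the stages together: validation, single-run
# optimization, condition scans, carrier-potential analysis and synthetic
# pathway generation, with serialized results and the resolved
# configuration written next to them.  A thin command-line wrapper lives in
# inst/scripts/pathmdf-cli.R.

#' Resolve a run configuration
#'
#' @param mode one of `"validate"`, `"optimize"`, `"scan"`, `"sweep"`,
#'   `"carriers"`, `"simulate"`.
#' @param pathway fixture id or path to a pathway file (ignored by
#'   `simulate`).
#' @param out output file (JSON for validate/optimize/simulate, CSV for
#'   scan/sweep/carriers); `NULL` returns results only.
#' @param co2,h2 clamped concentrations, mol/L.
#' @param epsilon translocations traded (scalar; `sweep` accepts a vector).
#' @param imposed_mdf driving-force floor, kJ/mol.
#' @param log10_h2,log10_co2 scan axes.
#' @param seed integer seed (used by `simulate`).
#' @param spec a [synthetic_spec()] for `simulate`.
#' @param ... further [env_conditions()] arguments.
#' @return a `pmdf_config` list.
#' @export
run_config <- function(mode = c("validate", "optimize", "scan", "sweep",
                                "carriers", "simulate"),
                       pathway = NULL, out = NULL, co2 = 1e-2, h2 = 1e-4,
                       epsilon = 0, imposed_mdf = 0,
                       log10_h2 = seq(-6, -1, by = 0.5),
                       log10_co2 = seq(-4, -1, by = 0.5),
                       seed = 1L, spec = NULL, ...) {
  cfg <- list(mode = match.arg(mode), pathway = pathway, out = out,
              co2 = co2, h2 = h2, epsilon = epsilon,
              imposed_mdf = imposed_mdf, log10_h2 = log10_h2,
              log10_co2 = log10_co2, seed = as.integer(seed), spec = spec,
              env_args = list(...))
  class(cfg) <- "pmdf_config"
  cfg
}

resolve_pathway <- function(id_or_path) {
  if (is.null(id_or_path)) stop("no pathway given", call. = FALSE)
  if (file.exists(id_or_path)) return(load_pathway(id_or_path))
  pathway_fixture(id_or_path)
}

#' Run the analysis pipeline
#'
#' Executes the configured stage and, when `out` is set, writes the result
#' (JSON or CSV) plus a `<out>.config.json` copy of the resolved
#' configuration for reproducibility.
#'
#' @param config a `pmdf_config` from [run_config()].
#' @return the result object, invisibly: a validation summary, a
#'   `pmdf_result`, a scan/sweep/ranges data.frame, or a generated
#'   `pmdf_pathway`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pmdf_config"))
  env <- do.call(env_conditions,
                 c(list(conc_CO2 = config$co2, conc_H2 = config$h2),
                   config$env_args))
  res <- switch(config$mode,
    validate = {
      p <- resolve_pathway(config$pathway)
      vs <- enumerate_variants(p)
      v <- vs[[1]]
      list(id = p$id, valid = TRUE,
           reactions = length(p$reactions),
           variants = length(vs),
           slp_cost = net_slp_cost(v),
           overall_dG0 = overall_stoichiometry(v)$dG0_prime,
           carbon_economy = carbon_atom_economy(v),
           declared = p$declared)
    },
    optimize = {
      p <- resolve_pathway(config$pathway)
      b <- best_variant(p, env, epsilon = config$epsilon,
                        imposed_mdf = config$imposed_mdf)
      r <- b$result
      if (r$status == "optimal") {
        r$carrier_assignment <- as.list(b$variant$carrier_assignment)
      }
      r
    },
    scan = atp_cost_grid(resolve_pathway(config$pathway),
                         log10_co2 = config$log10_co2,
                         log10_h2 = config$log10_h2,
                         imposed_mdf = config$imposed_mdf, env = env),
    sweep = tradeoff_sweep(resolve_pathway(config$pathway),
                           log10_h2 = config$log10_h2, co2 = config$co2,
                           epsilons = config$epsilon, env = env),
    carriers = carrier_range_scan(resolve_pathway(config$pathway), env,
                                  log10_h2 = config$log10_h2,
                                  epsilon = config$epsilon[1]),
    simulate = {
      spec <- config$spec
      if (is.null(spec)) stop("simulate needs a synthetic spec", call. = FALSE)
      spec$seed <- config$seed
      generate_pathway(spec)
    })
  if (!is.null(config$out)) {
    if (is.data.frame(res)) {
      utils::write.csv(res, config$out, row.names = FALSE)
    } else {
      obj <- if (inherits(res, "pmdf_result")) unclass(res) else
        if (inherits(res, "pmdf_pathway")) pathway_to_list(res) else res
      jsonlite::write_json(obj, config$out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    cfg <- config
    cfg$spec <- NULL
    jsonlite::write_json(unclass(cfg), paste0(config$out, ".config.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  invisible(res)
}

# serialize a pathway to the file schema (round-trips through load_pathway)
pathway_to_list <- function(p) {
  list(
    id = p$id, name = p$name, oxygen_class = p$oxygen_class,
    metabolites = lapply(unname(p$metabolites), function(m) {
      o <- list(id = m$id, name = m$name, carbon = m$carbon, role = m$role)
      if (!is.null(m$clamp)) o$clamp <- m$clamp
      o
    }),
    carriers = lapply(unname(p$carriers), function(cc)
      list(id = cc$id, E0_prime_V = cc$E0_prime_V, electrons = cc$electrons,
           ratio_bounds = cc$ratio_bounds)),
    reactions = lapply(unname(p$reactions), function(r) {
      o <- list(id = r$id, stoich = as.list(r$stoich),
                dG0_prime_kJ_mol = r$dG0_prime, slp_atp = r$slp_atp,
                cpt_capable = r$cpt_capable)
      if (r$flux != 1) o$flux <- r$flux
      if (!is.null(r$redox)) {
        o$redox <- list(n_e = r$redox$n_e,
                        carriers = as.list(r$redox$carriers),
                        direction = r$redox$direction)
      }
      o
    }),
    end_product = p$end_product,
    overall = if (!is.null(p$overall))
      list(stoich = p$overall$stoich,
           dG0_prime_kJ_mol = p$overall$dG0_prime),
    declared = p$declared
  )
}
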