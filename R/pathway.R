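# Pathway domain model: metabolites, reactions, electron carriers, pathways.
#
# Conventions
# -----------
# * Product stoichiometric coefficients are positive.
# * Redox reactions are stored in "hydrogen form": the reducing equivalents
#   are written as dissolved H2 (the terminal electron donor), with
#   coefficient -n_e/2 for reductions and +n_e/2 for oxidations.  Deriving a
#   variant substitutes the assigned carrier couple for the H2 and adds one
#   regeneration reaction per distinct carrier (EC_ox + H2 -> EC_red), so the
#   flux-weighted net transformation and total standard Gibbs energy of a
#   variant never depend on the carrier choice.
# * `dG0_prime` is the transformed reaction Gibbs energy at pH 7, ionic
#   strength 0.1 M, 298.15 K (eQuilibrator-style reference state); water and
#   H+ are fixed-activity species.
# * ATP/ADP/Pi never appear in stoichiometries: substrate-level
#   phosphorylation enters through `slp_atp`, folded into the equilibrium
#   constant of the step.
# * `flux` is the number of times a reaction runs per mole of end product
#   (1 unless a pathway merges two turns of a core cycle into one product).

parse_coef <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) && grepl("^\\s*-?[0-9]+\\s*/\\s*[0-9]+\\s*$", x)) {
    parts <- as.numeric(strsplit(x, "/")[[1]])
    return(parts[1] / parts[2])
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("cannot parse coefficient: ", x, call. = FALSE)
  v
}

new_metabolite <- function(id, name = id, carbon = 0,
                           role = c("internal", "clamped", "fixed_activity"),
                           clamp = NULL, note = NULL, bounds = NULL) {
  role <- match.arg(role)
  if (role != "clamped" && !is.null(clamp)) {
    stop("metabolite ", id, ": clamp value only allowed for role 'clamped'",
         call. = FALSE)
  }
  if (!is.null(clamp) && clamp <= 0) {
    stop("metabolite ", id, ": clamp value must be positive", call. = FALSE)
  }
  if (carbon < 0) stop("metabolite ", id, ": negative carbon count", call. = FALSE)
  # `bounds` overrides the environment concentration box for this variable
  # (dimensionless/log scale); used for potential pseudo-species.
  list(id = id, name = name, carbon = carbon, role = role,
       clamp = clamp, note = note, bounds = bounds)
}

new_carrier <- function(id, E0_prime_V, electrons = 2L,
                        ratio_bounds = c(1e-2, 1e2)) {
  stopifnot(length(ratio_bounds) == 2)
  if (any(ratio_bounds <= 0) || ratio_bounds[1] > ratio_bounds[2]) {
    stop("carrier ", id, ": invalid ratio bounds", call. = FALSE)
  }
  list(id = id, E0_prime_V = E0_prime_V, electrons = as.integer(electrons),
       ratio_bounds = as.numeric(ratio_bounds))
}

new_reaction <- function(id, stoich, dG0_prime, slp_atp = 0,
                         cpt_capable = FALSE, redox = NULL, flux = 1) {
  stoich <- vapply(stoich, parse_coef, numeric(1))
  stoich <- stoich[stoich != 0]
  if (!length(stoich)) stop("reaction ", id, ": empty stoichiometry", call. = FALSE)
  if (!slp_atp %in% c(0, 0.5, -0.5, 1, -1, 2, -2)) {
    stop("reaction ", id, ": slp_atp must be one of 0, ±1/2, ±1, ±2",
         call. = FALSE)
  }
  if (!is.null(redox)) {
    if (is.null(redox$n_e) || redox$n_e < 1) {
      stop("reaction ", id, ": redox record needs electrons_transferred >= 1",
           call. = FALSE)
    }
    if (!length(redox$carriers)) {
      stop("reaction ", id, ": redox record needs a non-empty carrier set",
           call. = FALSE)
    }
    redox$n_e <- as.integer(redox$n_e)
    redox$direction <- match.arg(redox$direction, c("reduction", "oxidation"))
  }
  list(id = id, stoich = stoich, dG0_prime = as.numeric(dG0_prime),
       slp_atp = slp_atp, cpt_capable = isTRUE(cpt_capable), redox = redox,
       flux = as.numeric(flux))
}

#' Assemble and validate a pathway object
#'
#' Used by [load_pathway()], the bundled fixtures and the synthetic-pathway
#' generator.  All structural invariants (known species, per-reaction carbon
#' balance, redox carrier sets, flux-weighted closure against the declared
#' overall equation) are checked here.
#'
#' @param x a list with fields `id`, `name`, `oxygen_class`, `metabolites`,
#'   `carriers`, `reactions`, `end_product`, `overall` and `declared`.
#' @return an object of class `pmdf_pathway`.
#' @export
as_pathway <- function(x) {
  p <- list(
    id = x$id, name = if (is.null(x$name)) x$id else x$name,
    oxygen_class = if (is.null(x$oxygen_class)) "anaerobic" else x$oxygen_class,
    metabolites = x$metabolites, carriers = x$carriers,
    reactions = x$reactions, end_product = x$end_product,
    overall = x$overall, declared = x$declared
  )
  names(p$metabolites) <- vapply(p$metabolites, `[[`, "", "id")
  names(p$carriers) <- vapply(p$carriers, `[[`, "", "id")
  names(p$reactions) <- vapply(p$reactions, `[[`, "", "id")
  class(p) <- "pmdf_pathway"
  validate_pathway(p)
  p
}

#' @rdname as_pathway
#' @param pathway a `pmdf_pathway`.
#' @export
validate_pathway <- function(pathway) {
  p <- pathway
  mets <- p$metabolites
  if (is.null(p$end_product) || !p$end_product %in% names(mets)) {
    stop("end_product must name a metabolite", call. = FALSE)
  }
  for (r in p$reactions) {
    unknown <- setdiff(names(r$stoich), names(mets))
    if (length(unknown)) {
      stop("reaction ", r$id, ": unknown species ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cbal <- sum(r$stoich * vapply(mets[names(r$stoich)], `[[`, 0, "carbon"))
    if (abs(cbal) > 1e-9) {
      stop("reaction ", r$id, ": carbon imbalance of ", cbal, " atoms",
           call. = FALSE)
    }
    if (!is.null(r$redox)) {
      bad <- setdiff(r$redox$carriers, names(p$carriers))
      if (length(bad)) {
        stop("reaction ", r$id, ": unknown carriers ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      for (cid in r$redox$carriers) {
        if (p$carriers[[cid]]$electrons != r$redox$n_e) {
          stop("reaction ", r$id, ": carrier ", cid, " transfers ",
               p$carriers[[cid]]$electrons, " electrons but the step needs ",
               r$redox$n_e, call. = FALSE)
        }
      }
    }
  }
  # flux-weighted net transformation must match the declared overall equation
  if (!is.null(p$overall)) {
    net <- pathway_net_stoich(p)
    decl <- vapply(p$overall$stoich, parse_coef, numeric(1))
    allsp <- union(names(net), names(decl))
    for (sp in allsp) {
      a <- if (sp %in% names(net)) net[[sp]] else 0
      b <- if (sp %in% names(decl)) decl[[sp]] else 0
      if (abs(a - b) > 1e-6) {
        stop("pathway ", p$id, ": net stoichiometry of ", sp, " is ", a,
             " but the overall equation declares ", b, call. = FALSE)
      }
    }
    dg <- sum(vapply(p$reactions, function(r) r$flux * r$dG0_prime, 0))
    if (!is.null(p$overall$dG0_prime) &&
        abs(dg - p$overall$dG0_prime) > 0.5) {
      stop("pathway ", p$id, ": elementary dG0' sum ", round(dg, 2),
           " differs from declared overall ", p$overall$dG0_prime,
           " by more than 0.5 kJ/mol", call. = FALSE)
    }
  }
  invisible(p)
}

# flux-weighted net stoichiometry over the hydrogen-form elementary reactions
pathway_net_stoich <- function(pathway) {
  net <- numeric(0)
  for (r in pathway$reactions) {
    for (sp in names(r$stoich)) {
      net[sp] <- (if (sp %in% names(net)) net[[sp]] else 0) +
        r$flux * r$stoich[[sp]]
    }
  }
  net[abs(net) > 1e-9]
}

#' Read a pathway definition file
#'
#' Pathway files are UTF-8 JSON with fields `id`, `name`, `oxygen_class`,
#' `metabolites`, `carriers`, `reactions`, `end_product`, `overall` and
#' `declared`; stoichiometric coefficients may be decimals or rational
#' strings such as `"1/2"`.  See the files under
#' `system.file("extdata", "pathways", package = "pathmdf")` for the schema.
#'
#' @param path file path.
#' @return a validated `pmdf_pathway`.
#' @export
load_pathway <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("id", "metabolites", "reactions", "end_product")) {
    if (is.null(x[[f]])) stop("pathway file missing field '", f, "'", call. = FALSE)
  }
  mets <- lapply(x$metabolites, function(m) {
    new_metabolite(m$id, if (is.null(m$name)) m$id else m$name,
                   if (is.null(m$carbon)) 0 else m$carbon,
                   if (is.null(m$role)) "internal" else m$role,
                   m$clamp, m$note)
  })
  carriers <- lapply(x$carriers, function(cc) {
    new_carrier(cc$id, cc$E0_prime_V,
                if (is.null(cc$electrons)) 2L else cc$electrons,
                if (is.null(cc$ratio_bounds)) c(1e-2, 1e2) else
                  unlist(cc$ratio_bounds))
  })
  reactions <- lapply(x$reactions, function(r) {
    redox <- r$redox
    if (!is.null(redox)) {
      redox <- list(n_e = redox$n_e, carriers = unlist(redox$carriers),
                    direction = if (is.null(redox$direction)) "reduction"
                                else redox$direction)
    }
    new_reaction(r$id, r$stoich, r$dG0_prime_kJ_mol,
                 if (is.null(r$slp_atp)) 0 else parse_coef(r$slp_atp),
                 isTRUE(r$cpt_capable), redox,
                 if (is.null(r$flux)) 1 else parse_coef(r$flux))
  })
  overall <- x$overall
  if (!is.null(overall)) {
    overall <- list(stoich = lapply(overall$stoich, parse_coef),
                    dG0_prime = overall$dG0_prime_kJ_mol)
  }
  as_pathway(list(id = x$id, name = x$name, oxygen_class = x$oxygen_class,
                  metabolites = mets, carriers = carriers,
                  reactions = reactions, end_product = x$end_product,
                  overall = overall, declared = x$declared))
}

#' @export
print.pmdf_pathway <- function(x, ...) {
  nred <- sum(vapply(x$reactions, function(r) !is.null(r$redox), TRUE))
  cat(sprintf("<pmdf_pathway> %s (%s, %s)\n", x$id, x$name, x$oxygen_class))
  cat(sprintf("  %d elementary reactions (%d redox), end product %s\n",
              length(x$reactions), nred, x$end_product))
  if (!is.null(x$declared)) {
    cat(sprintf("  declared: %s variants, SLP cost %s mol ATP/mol product\n",
                x$declared$variants, x$declared$slp_cost))
  }
  invisible(x)
}
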