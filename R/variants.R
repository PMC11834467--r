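# Variant derivation: concrete electron-carrier assignments closed by
# carrier regeneration against the terminal electron donor (H2).

# standard Gibbs energy of the regeneration reaction EC_ox + H2 -> EC_red
regen_dG0 <- function(carrier) {
  -carrier$electrons * FARADAY * (carrier$E0_prime_V - E0_H2_COUPLE)
}

#' Derive a variant from a carrier assignment
#'
#' Each redox step's hydrogen-form stoichiometry has its H2 replaced by the
#' assigned carrier couple; one regeneration reaction per distinct carrier
#' (`EC_ox + H2 -> EC_red`) closes the carrier balance, with a flux equal to
#' the net number of couples the pathway oxidizes per mole of product.
#'
#' @param pathway a `pmdf_pathway`.
#' @param assignment named character vector: redox reaction id -> carrier id.
#' @return an object of class `pmdf_variant`.
#' @export
make_variant <- function(pathway, assignment) {
  redox_ids <- names(which(vapply(pathway$reactions,
                                  function(r) !is.null(r$redox), TRUE)))
  missing <- setdiff(redox_ids, names(assignment))
  if (length(missing)) {
    stop("no carrier assigned for redox steps: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mets <- pathway$metabolites
  reactions <- list()
  couple_balance <- numeric(0)  # net couples oxidized per carrier
  for (r in pathway$reactions) {
    if (!is.null(r$redox)) {
      cid <- assignment[[r$id]]
      if (!cid %in% r$redox$carriers) {
        stop("carrier ", cid, " is not permissible for reaction ", r$id,
             call. = FALSE)
      }
      carrier <- pathway$carriers[[cid]]
      ncpl <- r$redox$n_e / carrier$electrons  # couples per catalytic event
      h <- if (r$redox$direction == "reduction") -ncpl else ncpl
      st <- r$stoich
      h2 <- if ("H2" %in% names(st)) st[["H2"]] else 0
      st[["H2"]] <- h2 - h          # remove the hydrogen written in the file
      red_id <- paste0(cid, "_red"); ox_id <- paste0(cid, "_ox")
      st[red_id] <- (if (red_id %in% names(st)) st[[red_id]] else 0) + h
      st[ox_id] <- (if (ox_id %in% names(st)) st[[ox_id]] else 0) - h
      st <- st[abs(st) > 1e-12]
      r2 <- r
      r2$stoich <- st
      r2$dG0_prime <- r$dG0_prime + h * regen_dG0(carrier)
      r2$carrier <- cid
      reactions[[r$id]] <- r2
      couple_balance[cid] <- (if (cid %in% names(couple_balance))
        couple_balance[[cid]] else 0) - h * r$flux
      for (sid in c(red_id, ox_id)) {
        if (!sid %in% names(mets)) {
          mets[[sid]] <- new_metabolite(sid, sid, carbon = 0, role = "internal")
        }
      }
    } else {
      reactions[[r$id]] <- r
    }
  }
  ratio_constraints <- list()
  for (cid in names(couple_balance)) {
    carrier <- pathway$carriers[[cid]]
    net <- couple_balance[[cid]]
    if (abs(net) > 1e-9) {
      sgn <- if (net > 0) 1 else -1  # net > 0: pathway oxidizes the carrier
      st <- c(-sgn, -abs(1), sgn)
      names(st) <- c(paste0(cid, "_ox"), "H2", paste0(cid, "_red"))
      if (sgn < 0) st[["H2"]] <- 1
      reactions[[paste0("regen_", cid)]] <- list(
        id = paste0("regen_", cid), stoich = st[abs(st) > 1e-12],
        dG0_prime = sgn * regen_dG0(carrier), slp_atp = 0,
        cpt_capable = FALSE, redox = NULL, flux = abs(net),
        is_regen = TRUE, carrier = cid)
    }
    ratio_constraints[[cid]] <- list(
      carrier = cid, red = paste0(cid, "_red"), ox = paste0(cid, "_ox"),
      ratio_bounds = carrier$ratio_bounds)
  }
  v <- list(pathway_id = pathway$id, pathway_name = pathway$name,
            carrier_assignment = assignment[redox_ids],
            metabolites = mets, carriers = pathway$carriers,
            reactions = reactions, end_product = pathway$end_product,
            overall = pathway$overall,
            ratio_constraints = ratio_constraints)
  class(v) <- "pmdf_variant"
  v
}

#' Enumerate all carrier-assignment variants of a pathway
#'
#' The Cartesian product of the permissible carrier sets over the redox
#' steps, in deterministic order (the carrier of the first redox step varies
#' slowest).  Variants are distinct iff their assignments differ.
#'
#' @param pathway a `pmdf_pathway`.
#' @return list of `pmdf_variant`.
#' @export
enumerate_variants <- function(pathway) {
  redox <- Filter(function(r) !is.null(r$redox), pathway$reactions)
  if (!length(redox)) {
    return(list(make_variant(pathway, character(0))))
  }
  sets <- lapply(redox, function(r) r$redox$carriers)
  names(sets) <- vapply(redox, `[[`, "", "id")
  grid <- rev(expand.grid(rev(sets), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(i) {
    a <- vapply(grid[i, , drop = FALSE], as.character, "")
    names(a) <- names(sets)
    make_variant(pathway, a)
  })
}

#' Net ATP cost of a variant via substrate-level phosphorylation
#'
#' Negative of the flux-weighted sum of per-step `slp_atp`, in mol ATP per
#' mol end product.  Matches the "ATP cost via SLP" pathway aggregate.
#'
#' @param variant a `pmdf_variant`.
#' @export
net_slp_cost <- function(variant) {
  -sum(vapply(variant$reactions, function(r) r$flux * r$slp_atp, 0))
}

#' Net overall transformation of a closed variant
#'
#' Flux-weighted sum over all reactions including carrier regenerations.
#' Carriers and internal intermediates must cancel; a non-cancelling
#' internal species is a closure error.
#'
#' @param variant a `pmdf_variant`.
#' @return a reaction-like list with `stoich` and `dG0_prime`.
#' @export
overall_stoichiometry <- function(variant) {
  net <- numeric(0)
  dg <- 0
  for (r in variant$reactions) {
    dg <- dg + r$flux * r$dG0_prime
    for (sp in names(r$stoich)) {
      net[sp] <- (if (sp %in% names(net)) net[[sp]] else 0) +
        r$flux * r$stoich[[sp]]
    }
  }
  net <- net[abs(net) > 1e-9]
  carrier_sp <- unlist(lapply(variant$ratio_constraints,
                              function(rc) c(rc$red, rc$ox)))
  decl <- if (!is.null(variant$overall)) names(variant$overall$stoich) else
    names(net)
  bad <- setdiff(names(net), decl)
  bad <- intersect(bad, c(carrier_sp,
                          names(which(vapply(variant$metabolites, function(m)
                            m$role == "internal", TRUE)))))
  bad <- setdiff(bad, variant$end_product)
  if (length(bad)) {
    stop("variant does not close: species ", paste(bad, collapse = ", "),
         " do not cancel", call. = FALSE)
  }
  list(id = paste0(variant$pathway_id, "_overall"), stoich = as.list(net),
       dG0_prime = dg)
}

#' Carbon atom economy of a variant
#'
#' Carbon atoms in the end product divided by carbon atoms in the CO2
#' consumed gross (flux-weighted sum of CO2 consumption over carboxylation
#' steps; CO2 released mid-pathway lowers the economy below 1).
#'
#' @param variant a `pmdf_variant`.
#' @return fraction in (0, 1].
#' @export
carbon_atom_economy <- function(variant) {
  gross <- 0
  for (r in variant$reactions) {
    co2 <- if ("CO2" %in% names(r$stoich)) r$stoich[["CO2"]] else 0
    if (co2 < 0) gross <- gross - r$flux * co2
  }
  if (gross <= 0) stop("variant consumes no CO2", call. = FALSE)
  net <- overall_stoichiometry(variant)
  nprod <- net$stoich[[variant$end_product]]
  prod_c <- variant$metabolites[[variant$end_product]]$carbon * nprod
  prod_c / gross
}

#' @export
print.pmdf_variant <- function(x, ...) {
  cat(sprintf("<pmdf_variant> of %s\n", x$pathway_id))
  if (length(x$carrier_assignment)) {
    cat("  carriers:",
        paste(names(x$carrier_assignment), x$carrier_assignment,
              sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  %d reactions incl. %d carrier regenerations\n",
              length(x$reactions),
              sum(vapply(x$reactions, function(r) isTRUE(r$is_regen), TRUE))))
  invisible(x)
}
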