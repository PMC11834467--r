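# Build the encoded pathway fixtures under inst/extdata/pathways/.
#
# Run from the package root:  Rscript data-raw/build_fixtures.R
#
# Each pathway is entered as a compact reaction table.  The script
# (1) checks per-reaction carbon balance and internal-species flux closure,
# (2) pads fixed-activity species (H2O, H+) on one designated reaction so the
#     flux-weighted net matches the declared overall equation,
# (3) reconciles per-step dG0' so their flux-weighted sum equals the declared
#     overall standard Gibbs energy exactly (one designated step absorbs the
#     residual),
# (4) verifies the declared aggregates (variant count, SLP cost, reaction
#     count) and writes strict-UTF-8 JSON.

suppressMessages(devtools::load_all(".", quiet = TRUE))

CARBON <- c(
  CO2 = 1, HCO3 = 1, CO = 1, formate = 1, H2 = 0, H2O = 0, `H+` = 0,
  Pi = 0, PPi = 0, CoA = 0, AcCoA = 2,
  # rTCA / shared TCA-type intermediates
  citrate = 6, citrylCoA = 6, cisaconitate = 6, isocitrate = 6,
  oxalosuccinate = 6, KGA = 5, succinylCoA = 4, succinate = 4, fumarate = 4,
  malate = 4, OAA = 4, pyruvate = 3, PEP = 3, malylCoA = 4, glyoxylate = 2,
  # WL cofactor-bound C1 species
  MFR = 0, formylMFR = 1, H4MPT = 0, formylH4MPT = 1, methenylH4MPT = 1,
  methyleneH4MPT = 1, methylH4MPT = 1, CoFeSP = 0, methylCoFeSP = 1,
  acetylCoFeSP = 2, H4F = 0, formylH4F = 1, methenylH4F = 1,
  methyleneH4F = 1, methylH4F = 1,
  # 3HP / 4HB intermediates
  malonylCoA = 3, MSA = 3, MSA_hydrate = 3, `3HP` = 3, `3HPCoA` = 3,
  acryloylCoA = 3, propionylCoA = 3, MMCoA = 4, MMCoAr = 4, SSA = 4,
  SSA_hydrate = 4, `4HB` = 4, `4HBP` = 4, `4HBCoA` = 4, vinylacetylCoA = 4,
  crotonylCoA = 4, `3HBCoA` = 4, acetoacetylCoA = 4,
  # bicycle second cycle
  methylmalylCoA = 5, mesaconylC1CoA = 5, mesaconylC4CoA = 5,
  citramalylCoA = 5, citramalylCoAr = 5, malylP = 4,
  # CETCH
  ethylmalonylCoA = 5, ethylmalonylCoAr = 5, methylsuccinylCoA = 5,
  # glyoxylate assimilation
  TSA = 3, glycerate = 3, glycolate = 2, glycolylCoA = 2
)
CLAMPED <- c("CO2", "H2")
FIXED <- c("H2O", "H+", "Pi", "PPi")

CARRIERS <- list(
  NAD = list(id = "NAD", E0_prime_V = -0.320, electrons = 2),
  NADP = list(id = "NADP", E0_prime_V = -0.380, electrons = 2),
  FAD = list(id = "FAD", E0_prime_V = -0.220, electrons = 2),
  Fd = list(id = "Fd", E0_prime_V = -0.400, electrons = 2),
  quinone = list(id = "quinone", E0_prime_V = -0.075, electrons = 2),
  F420 = list(id = "F420", E0_prime_V = -0.360, electrons = 2)
)

parse_eq <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  stopifnot(length(sides) == 2)
  parse_side <- function(s, sgn) {
    terms <- strsplit(trimws(s), " + ", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (t in trimws(terms)) {
      if (!nzchar(t)) next
      m <- regmatches(t, regexec("^([0-9.]+ )?(.+)$", t))[[1]]
      coef <- if (nzchar(trimws(m[2]))) as.numeric(m[2]) else 1
      sp <- trimws(m[3])
      out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0) + sgn * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  all <- c(lhs, rhs)
  tapply(all, names(all), sum)
}

# rx(id, equation, dG0 guess, slp, cpt, carriers (redox set), direction, flux)
rx <- function(id, eq, dg, slp = 0, cpt = FALSE, red = NULL,
               dir = "reduction", flux = 1) {
  list(id = id, eq = eq, dg = dg, slp = slp, cpt = cpt, red = red,
       dir = dir, flux = flux)
}

build_fixture <- function(id, name, oxy, rxs, end_product, overall_eq,
                          overall_dg, declared, dg_balance, pad_balance) {
  stoichs <- lapply(rxs, function(r) parse_eq(r$eq))
  names(stoichs) <- vapply(rxs, `[[`, "", "id")
  species <- unique(unlist(lapply(stoichs, names)))
  unknown <- setdiff(species, names(CARBON))
  if (length(unknown)) stop(id, ": unknown species ", paste(unknown, collapse = ", "))
  # carbon balance per reaction
  for (i in seq_along(rxs)) {
    bal <- sum(stoichs[[i]] * CARBON[names(stoichs[[i]])])
    if (abs(bal) > 1e-9) stop(id, "/", rxs[[i]]$id, ": carbon imbalance ", bal)
  }
  decl_net <- parse_eq(overall_eq)
  flux <- vapply(rxs, `[[`, 0, "flux")
  net <- numeric(0)
  for (i in seq_along(rxs)) for (sp in names(stoichs[[i]])) {
    net[sp] <- (if (sp %in% names(net)) net[[sp]] else 0) +
      flux[i] * stoichs[[i]][[sp]]
  }
  allsp <- union(names(net), names(decl_net))
  diff <- setNames(numeric(length(allsp)), allsp)
  for (sp in allsp) {
    diff[sp] <- (if (sp %in% names(decl_net)) decl_net[[sp]] else 0) -
      (if (sp %in% names(net)) net[[sp]] else 0)
  }
  diff <- diff[abs(diff) > 1e-9]
  if (length(setdiff(names(diff), FIXED))) {
    stop(id, ": net mismatch on non-fixed species: ",
         paste(names(diff), round(diff, 3), collapse = ", "))
  }
  if (length(diff)) {
    bi <- match(pad_balance, names(stoichs))
    if (flux[bi] != 1) stop(id, ": pad-balance reaction must have flux 1")
    for (sp in names(diff)) {
      cur <- if (sp %in% names(stoichs[[bi]])) stoichs[[bi]][[sp]] else 0
      stoichs[[bi]][sp] <- cur + diff[[sp]]
    }
    message(sprintf("  %s: padded %s with %s", id, pad_balance,
                    paste(names(diff), sprintf("%+g", diff), collapse = " ")))
  }
  dgs <- vapply(rxs, `[[`, 0, "dg")
  resid <- overall_dg - sum(flux * dgs)
  bi <- match(dg_balance, names(stoichs))
  if (anyNA(bi)) stop(id, ": unknown dg-balance reaction")
  adj <- resid / sum(flux[bi])
  if (abs(adj) > 40) stop(id, ": dG0 residual too large (", round(adj, 1),
                          " per balance step)")
  dgs[bi] <- dgs[bi] + adj
  message(sprintf("  %s: dG0 residual %+.1f spread over %s (%+.2f each)",
                  id, resid, paste(dg_balance, collapse = ","), adj))
  # variant count
  sizes <- vapply(rxs, function(r) if (is.null(r$red)) 1L else length(r$red), 1L)
  nvar <- prod(sizes)
  if (nvar != declared$variants) {
    stop(id, ": variant count ", nvar, " != declared ", declared$variants)
  }
  slp_cost <- -sum(flux * vapply(rxs, `[[`, 0, "slp"))
  if (abs(slp_cost - declared$slp_cost) > 1e-9) {
    stop(id, ": SLP cost ", slp_cost, " != declared ", declared$slp_cost)
  }
  if (length(rxs) != declared$reactions) {
    stop(id, ": ", length(rxs), " reactions != declared ", declared$reactions)
  }
  carrier_ids <- unique(unlist(lapply(rxs, `[[`, "red")))
  role_of <- function(sp) {
    if (sp %in% CLAMPED) "clamped" else if (sp %in% FIXED) "fixed_activity"
    else "internal"
  }
  species <- unique(unlist(lapply(stoichs, names)))
  out <- list(
    id = id, name = name, oxygen_class = oxy,
    metabolites = lapply(species, function(sp)
      list(id = sp, carbon = CARBON[[sp]], role = role_of(sp))),
    carriers = lapply(unname(CARRIERS[carrier_ids]), function(cc)
      c(cc, list(ratio_bounds = c(1e-2, 1e2)))),
    reactions = lapply(seq_along(rxs), function(i) {
      r <- rxs[[i]]
      o <- list(id = r$id, stoich = as.list(stoichs[[i]]),
                dG0_prime_kJ_mol = round(dgs[i], 4), slp_atp = r$slp,
                cpt_capable = r$cpt)
      if (r$flux != 1) o$flux <- r$flux
      if (!is.null(r$red)) {
        o$redox <- list(n_e = 2, carriers = as.list(r$red), direction = r$dir)
      }
      o
    }),
    end_product = end_product,
    overall = list(stoich = as.list(decl_net), dG0_prime_kJ_mol = overall_dg),
    declared = declared
  )
  path <- file.path("inst/extdata/pathways", paste0(id, ".json"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # round-trip through the package loader (runs all invariant checks)
  p <- load_pathway(path)
  stopifnot(length(enumerate_variants(p)) == declared$variants)
  v <- enumerate_variants(p)[[1]]
  stopifnot(abs(net_slp_cost(v) - declared$slp_cost) < 1e-9,
            abs(overall_stoichiometry(v)$dG0_prime - overall_dg) < 0.5)
  invisible(p)
}

AC <- "2 CO2 + 4 H2 + CoA -> AcCoA + 3 H2O"            # acetyl-CoA pathways
PYR <- "3 CO2 + 5 H2 -> pyruvate + 4 H2O + H+"          # pyruvate end product
GLYC <- "3 CO2 + 5 H2 -> glycerate + 2 H2O + H+"        # glycerate end product

message("rTCA")
build_fixture(
  "rtca", "Reverse TCA cycle", "anaerobic",
  list(
    rx("ccl1", "citrate + CoA -> citrylCoA", 35.0, slp = -1),
    rx("ccl2", "citrylCoA -> OAA + AcCoA", 5.0),
    rx("oaa_red", "OAA + H2 -> malate", -47.9, cpt = TRUE,
       red = c("NAD", "NADP", "FAD")),
    rx("fum_hyd", "malate -> fumarate + H2O", 3.6),
    rx("fum_red", "fumarate + H2 -> succinate", -85.9, cpt = TRUE,
       red = c("quinone", "FAD", "NAD")),
    rx("scs", "succinate + CoA -> succinylCoA", 35.0, slp = -1),
    rx("kga_synth", "succinylCoA + CO2 + H2 -> KGA + CoA + H2O", -13.5,
       red = c("Fd", "NAD")),
    rx("kga_carbox", "KGA + CO2 -> oxalosuccinate", 5.0),
    rx("oxs_red", "oxalosuccinate + H2 -> isocitrate", -82.0, cpt = TRUE,
       red = c("NAD", "NADP", "Fd")),
    rx("acn_a", "isocitrate -> cisaconitate + H2O", 6.0),
    rx("acn_b", "cisaconitate + H2O -> citrate", -14.0)
  ),
  "AcCoA", AC, -142.3,
  list(slp_cost = 2, variants = 54, reactions = 11),
  dg_balance = "oxs_red", pad_balance = "ccl1")

message("Methanogenic WL")
build_fixture(
  "wl_methanogenic", "Methanogenic Wood-Ljungdahl pathway", "anaerobic",
  list(
    rx("fmd", "CO2 + H2 + MFR -> formylMFR + H2O", 16.0, cpt = TRUE,
       red = "Fd"),
    rx("ftr", "formylMFR + H4MPT -> formylH4MPT + MFR", -4.4),
    rx("mch", "formylH4MPT -> methenylH4MPT + H2O", -4.6),
    rx("mtd", "methenylH4MPT + H2 -> methyleneH4MPT", -30.0, red = "F420"),
    rx("mer", "methyleneH4MPT + H2 -> methylH4MPT", -40.0, red = "F420"),
    rx("mtr", "methylH4MPT + CoFeSP -> methylCoFeSP + H4MPT", -30.0,
       cpt = TRUE),
    rx("codh", "CO2 + H2 -> CO + H2O", 12.0, red = "Fd"),
    rx("acs_a", "methylCoFeSP + CO -> acetylCoFeSP", -49.8),
    rx("acs_b", "acetylCoFeSP + CoA -> AcCoA + CoFeSP", -20.0)
  ),
  "AcCoA", AC, -142.3,
  list(slp_cost = 0, variants = 1, reactions = 9),
  dg_balance = "acs_a", pad_balance = "acs_b")

message("Acetogenic WL")
build_fixture(
  "wl_acetogenic", "Acetogenic Wood-Ljungdahl pathway", "anaerobic",
  list(
    rx("fdh", "CO2 + H2 -> formate", 1.2, red = c("NAD", "NADP", "Fd")),
    rx("fhs", "formate + H4F -> formylH4F + H2O", 25.0, slp = -1),
    rx("mtc", "formylH4F -> methenylH4F + H2O", -2.0),
    rx("mtd2", "methenylH4F + H2 -> methyleneH4F", -22.0,
       red = c("NAD", "NADP")),
    rx("mtr2", "methyleneH4F + H2 -> methylH4F", -41.3, cpt = TRUE,
       red = c("NAD", "Fd")),
    rx("mtrs", "methylH4F + CoFeSP -> methylCoFeSP + H4F", -35.0),
    rx("codh2", "CO2 + H2 -> CO + H2O", 12.0, cpt = TRUE, red = "Fd"),
    rx("acs_a2", "methylCoFeSP + CO -> acetylCoFeSP", -68.7),
    rx("acs_b2", "acetylCoFeSP + CoA -> AcCoA + CoFeSP", -20.0)
  ),
  "AcCoA", AC, -142.3,
  list(slp_cost = 1, variants = 12, reactions = 9),
  dg_balance = "acs_a2", pad_balance = "acs_b2")

message("DCHB")
build_fixture(
  "dchb", "Dicarboxylate hydroxybutyrate cycle", "anaerobic",
  list(
    rx("pfor", "AcCoA + CO2 + H2 -> pyruvate + CoA + H2O", 16.6,
       red = c("Fd", "NAD")),
    rx("ppsk", "pyruvate -> PEP", 61.9, slp = -2),
    rx("ca", "CO2 + H2O -> HCO3", -4.0),
    rx("ppc", "PEP + HCO3 -> OAA + H2O", -30.0),
    rx("mdh", "OAA + H2 -> malate", -47.9, cpt = TRUE,
       red = c("NAD", "NADP", "FAD")),
    rx("fum_hyd", "malate -> fumarate + H2O", 3.6),
    rx("fum_red", "fumarate + H2 -> succinate", -85.9, cpt = TRUE,
       red = c("quinone", "FAD", "NAD")),
    rx("scs", "succinate + CoA -> succinylCoA", 35.0, slp = -1),
    rx("ssadh", "succinylCoA + H2 -> SSA + CoA", -15.0,
       red = c("NADP", "NAD")),
    rx("ssar", "SSA + H2 -> 4HB", -25.0, cpt = TRUE,
       red = c("NAD", "NADP", "quinone")),
    rx("hbcl", "4HB + CoA -> 4HBCoA", 35.0, slp = -0.5),
    rx("hbd_a", "4HBCoA -> vinylacetylCoA + H2O", 10.0),
    rx("hbd_b", "vinylacetylCoA -> crotonylCoA", -10.0),
    rx("ech", "crotonylCoA + H2O -> 3HBCoA", -3.0),
    rx("hbdh", "3HBCoA -> acetoacetylCoA + H2", 31.6, dir = "oxidation",
       red = c("NAD", "NADP")),
    rx("thl", "acetoacetylCoA + CoA -> 2 AcCoA", -25.0)
  ),
  "AcCoA", AC, -142.3,
  list(slp_cost = 3.5, variants = 216, reactions = 16),
  dg_balance = c("ssadh", "ssar", "hbcl", "ppsk"), pad_balance = "thl")

message("3HP-4HB")
build_fixture(
  "hp4hb", "Hydroxypropionate hydroxybutyrate cycle", "aerobic",
  list(
    rx("ca", "2 CO2 + 2 H2O -> 2 HCO3", -8.0),
    rx("acc", "AcCoA + HCO3 -> malonylCoA + H2O", 20.0, slp = -1),
    rx("mcr1", "malonylCoA + H2 -> MSA + CoA", -15.0, red = c("NADP", "NAD")),
    rx("mcr2", "MSA + H2 -> 3HP", -30.0, red = c("NADP", "NAD")),
    rx("pcs1", "3HP + CoA -> 3HPCoA", 35.0, slp = -2),
    rx("pcs2", "3HPCoA -> acryloylCoA + H2O", 5.0),
    rx("pcs3", "acryloylCoA + H2 -> propionylCoA", -79.9, cpt = TRUE,
       red = c("NADP", "FAD")),
    rx("pcc", "propionylCoA + HCO3 -> MMCoA + H2O", 20.0, slp = -1),
    rx("mcm", "MMCoA -> succinylCoA", -7.0),
    rx("ssadh", "succinylCoA + H2 -> SSA + CoA", -35.0,
       red = c("NADP", "NAD")),
    rx("ssar", "SSA + H2 -> 4HB", -45.0, cpt = TRUE, red = c("NAD", "NADP")),
    rx("hbcl", "4HB + CoA -> 4HBCoA", 30.0, slp = -1),
    rx("hbd_a", "4HBCoA -> vinylacetylCoA + H2O", 0.0),
    rx("hbd_b", "vinylacetylCoA -> crotonylCoA", -10.0),
    rx("ech", "crotonylCoA + H2O -> 3HBCoA", -3.0),
    rx("hbdh", "3HBCoA -> acetoacetylCoA + H2", 31.6, dir = "oxidation",
       red = "NAD"),
    rx("thl", "acetoacetylCoA + CoA -> 2 AcCoA", -25.0)
  ),
  "AcCoA", AC, -142.3,
  list(slp_cost = 5, variants = 32, reactions = 17),
  dg_balance = c("mcr1", "mcr2", "pcs1", "thl"), pad_balance = "thl")

message("3HP bicycle")
build_fixture(
  "hp_bicycle", "Hydroxypropionate bicycle", "aerobic",
  list(
    rx("ca1", "CO2 + H2O -> HCO3", -4.0, flux = 2),
    rx("acc", "AcCoA + HCO3 -> malonylCoA + H2O", 20.0, slp = -1, flux = 2),
    rx("mcr1", "malonylCoA + H2 -> MSA + CoA", -15.0, flux = 2,
       red = c("NADP", "NAD")),
    rx("mcr2", "MSA + H2 -> 3HP", -30.0, flux = 2, red = c("NADP", "NAD")),
    rx("pcs1", "3HP + CoA -> 3HPCoA", 35.0, slp = -1, flux = 2),
    rx("pcs2", "3HPCoA -> acryloylCoA + H2O", 5.0, flux = 2),
    rx("pcs3", "acryloylCoA + H2 -> propionylCoA", -79.9, cpt = TRUE,
       flux = 2, red = c("NADP", "NAD", "FAD")),
    rx("ca2", "CO2 + H2O -> HCO3", -4.0),
    rx("pcc", "propionylCoA + HCO3 -> MMCoA + H2O", 20.0, slp = -1),
    rx("epim", "MMCoA -> MMCoAr", 0.0),
    rx("mcm", "MMCoAr -> succinylCoA", -7.0),
    rx("sch", "succinylCoA + H2O -> succinate + CoA", -35.0),
    rx("sdh", "succinate -> fumarate + H2", 85.9, cpt = TRUE,
       dir = "oxidation", red = "NAD"),
    rx("fum_hyd", "fumarate + H2O -> malate", -3.6),
    rx("mtk", "malate + CoA -> malylCoA", 35.0, slp = -1),
    rx("mcl1", "malylCoA -> AcCoA + glyoxylate", 10.0),
    rx("mmcl", "propionylCoA + glyoxylate -> methylmalylCoA", -15.0),
    rx("mcd", "methylmalylCoA -> mesaconylC1CoA + H2O", 0.0),
    rx("mct", "mesaconylC1CoA -> mesaconylC4CoA", 0.0),
    rx("meh", "mesaconylC4CoA + H2O -> citramalylCoA", -5.0),
    rx("cmt", "citramalylCoA -> citramalylCoAr", 0.0),
    rx("ccl", "citramalylCoAr -> AcCoA + pyruvate", 5.0)
  ),
  "pyruvate", PYR, -113.6,
  list(slp_cost = 6, variants = 12, reactions = 22),
  dg_balance = c("acc", "mcr2", "mtk", "pcs1"), pad_balance = "ccl")

message("Via pyruvate (tartronate semialdehyde route)")
build_fixture(
  "via_pyruvate_ts", "Via pyruvate (tartronate semialdehyde route)",
  "anaerobic",
  list(
    rx("pfor", "AcCoA + CO2 + H2 -> pyruvate + CoA + H2O", 16.6, cpt = TRUE,
       red = c("Fd", "NAD")),
    rx("pps", "pyruvate -> PEP + PPi", 11.9, slp = -1),
    rx("ppa", "PPi -> 2 Pi", -21.9),
    rx("ca", "CO2 + H2O -> HCO3", -4.0),
    rx("ppc", "PEP + HCO3 -> OAA + H2O", -30.0),
    rx("mdh", "OAA + H2 -> malate", -47.9, cpt = TRUE,
       red = c("NAD", "NADP", "FAD")),
    rx("mtk", "malate + CoA -> malylCoA", 30.0, slp = -1),
    rx("mcl", "malylCoA -> AcCoA + glyoxylate", 0.0),
    rx("kgs2", "succinate + CO2 + H2 -> KGA + H2O", -5.0, cpt = TRUE,
       red = "Fd"),
    rx("kgc", "KGA + CO2 -> oxalosuccinate", 0.0),
    rx("idh", "oxalosuccinate + H2 -> isocitrate", -30.0, cpt = TRUE,
       red = "NAD"),
    rx("icl", "isocitrate -> succinate + glyoxylate", 0.0),
    rx("tsa_s", "2 glyoxylate -> TSA + CO2", -20.0),
    rx("tsa_r", "TSA + H2 -> glycerate", -30.0, red = c("NAD", "NADP"))
  ),
  "glycerate", "3 CO2 + 5 H2 -> glycerate + 2 H2O + H+ + 2 Pi", -80.6,
  list(slp_cost = 2, variants = 12, reactions = 14),
  dg_balance = c("pps", "mcl"), pad_balance = "tsa_s")

message("Via citrate (tartronate semialdehyde route)")
build_fixture(
  "via_citrate_ts", "Via citrate (tartronate semialdehyde route)",
  "anaerobic",
  list(
    rx("ccs", "OAA + AcCoA -> citrylCoA", 0.0),
    rx("cglyl", "citrylCoA -> succinylCoA + glyoxylate", 5.0),
    rx("kgs", "succinylCoA + CO2 + H2 -> KGA + CoA + H2O", -13.5,
       red = "Fd"),
    rx("kgc2", "KGA + CO2 -> oxalosuccinate", 5.0),
    rx("idh2", "oxalosuccinate + H2 -> isocitrate", -30.0, red = "NAD"),
    rx("acn_a", "isocitrate -> cisaconitate + H2O", 6.0),
    rx("acn_b", "cisaconitate + H2O -> citrate", -14.0),
    rx("cl3", "citrate + CoA -> OAA + AcCoA", -5.0, slp = -1),
    rx("pfor2", "AcCoA + CO2 + H2 -> pyruvate + CoA + H2O", 16.6,
       red = c("Fd", "NAD")),
    rx("me", "pyruvate + CO2 + H2 -> malate", -25.0, cpt = TRUE,
       red = c("NAD", "NADP", "FAD")),
    rx("mtk3", "malate + CoA -> malylCoA", 35.0, slp = -1),
    rx("mcl2", "malylCoA -> AcCoA + glyoxylate", 5.0),
    rx("tsa_s", "2 glyoxylate -> TSA + CO2", -20.0),
    rx("tsa_r", "TSA + H2 -> glycerate", -30.0, red = c("NAD", "NADP"))
  ),
  "glycerate", GLYC, -80.6,
  list(slp_cost = 2, variants = 12, reactions = 14),
  dg_balance = c("me", "idh2", "tsa_r"), pad_balance = "tsa_s")

via_malonyl_core <- list(
  rx("ca1", "CO2 + H2O -> HCO3", -4.0, flux = 2),
  rx("ca2", "CO2 + H2O -> HCO3", -4.0, flux = 2),
  rx("acc", "AcCoA + HCO3 -> malonylCoA + H2O", 20.0, slp = -1, flux = 2),
  rx("mcr1", "malonylCoA + H2 -> MSA + CoA", -15.0, flux = 2,
     red = c("NADP", "NAD")),
  rx("msa_h", "MSA + H2O -> MSA_hydrate", -1.0, flux = 2),
  rx("mcr2", "MSA_hydrate + H2 -> 3HP + H2O", -29.0, flux = 2,
     red = "NADP"),
  rx("pcs1", "3HP + CoA -> 3HPCoA", 35.0, slp = -1, flux = 2),
  rx("pcs2", "3HPCoA -> acryloylCoA + H2O", 5.0, flux = 2),
  rx("pcs3", "acryloylCoA + H2 -> propionylCoA", -79.9, cpt = TRUE,
     flux = 2, red = "NADP"),
  rx("pcc", "propionylCoA + HCO3 -> MMCoA + H2O", 20.0, slp = -1, flux = 2),
  rx("epim", "MMCoA -> MMCoAr", 0.0, flux = 2),
  rx("mcm", "MMCoAr -> succinylCoA", -7.0, flux = 2),
  rx("sch", "succinylCoA + H2O -> succinate + CoA", -35.0, flux = 2),
  rx("sdh_ox", "succinate -> fumarate + H2", 85.9, cpt = TRUE, flux = 2,
     dir = "oxidation", red = "NAD"),
  rx("fum_hyd", "fumarate + H2O -> malate", -3.6, flux = 2),
  rx("mtk2a", "malate -> malylP", 10.0, slp = -0.5, flux = 2),
  rx("mtk2b", "malylP + CoA -> malylCoA", 5.0, flux = 2),
  rx("mcl", "malylCoA -> AcCoA + glyoxylate", 10.0, flux = 2)
)
ts_block <- list(
  rx("tsa_s", "2 glyoxylate -> TSA + CO2", -20.0),
  rx("tsa_r", "TSA + H2 -> glycerate", -30.0, red = c("NAD", "NADP"))
)
gs_block <- list(
  rx("gr1", "glyoxylate + H2 -> glycolate", -30.0,
     red = c("NAD", "NADP", "Fd")),
  rx("gr2", "glycolate + CoA -> glycolylCoA", 35.0, slp = -1),
  rx("gr3", "glycolylCoA + H2 -> AcCoA + H2O", -40.0,
     red = c("NAD", "NADP", "FAD")),
  rx("gs_ms", "AcCoA + glyoxylate -> malate + CoA", -30.0),
  rx("gs_me", "malate -> pyruvate + CO2 + H2", 16.2, dir = "oxidation",
     red = c("NAD", "NADP"))
)

message("Via malonyl-CoA (tartronate semialdehyde route)")
build_fixture(
  "via_malonyl_ts", "Via malonyl-CoA (tartronate semialdehyde route)",
  "aerobic", c(via_malonyl_core, ts_block),
  "glycerate", GLYC, -80.6,
  list(slp_cost = 7, variants = 4, reactions = 20),
  dg_balance = c("mcr1", "mcr2", "acc", "pcc"), pad_balance = "tsa_s")

message("Via malonyl-CoA (glyoxylate shunt route)")
build_fixture(
  "via_malonyl_gs", "Via malonyl-CoA (glyoxylate shunt route)",
  "aerobic", c(via_malonyl_core, gs_block),
  "pyruvate", PYR, -113.6,
  list(slp_cost = 8, variants = 36, reactions = 23),
  dg_balance = c("mcr1", "mcr2", "acc", "pcc", "gr1", "gr3"),
  pad_balance = "gs_me")

cetch_core <- list(
  rx("ccr", "crotonylCoA + CO2 + H2 -> ethylmalonylCoA", -20.0, flux = 2,
     red = "NADP"),
  rx("eep", "ethylmalonylCoA -> ethylmalonylCoAr", 0.0, flux = 2),
  rx("eem", "ethylmalonylCoAr -> methylsuccinylCoA", -5.0, flux = 2),
  rx("msd", "methylsuccinylCoA -> mesaconylC1CoA + H2", 55.0, cpt = TRUE,
     flux = 2, dir = "oxidation", red = c("NAD", "NADP")),
  rx("mtc2", "mesaconylC1CoA -> mesaconylC4CoA", 0.0, flux = 2),
  rx("mch", "mesaconylC4CoA + H2O -> methylmalylCoA", -5.0, flux = 2),
  rx("mml", "methylmalylCoA -> propionylCoA + glyoxylate", 15.0, flux = 2),
  rx("ca3", "CO2 + H2O -> HCO3", -4.0, slp = -0.5, flux = 2),
  rx("pcc2", "propionylCoA + HCO3 -> MMCoA + H2O", 20.0, slp = -1, flux = 2),
  rx("epim2", "MMCoA -> MMCoAr", 0.0, flux = 2),
  rx("mcm2", "MMCoAr -> succinylCoA", -7.0, flux = 2),
  rx("ssr", "succinylCoA + H2 -> SSA + CoA", -15.0, flux = 2,
     red = c("NADP", "NAD")),
  rx("ssa_h", "SSA + H2O -> SSA_hydrate", -1.0, flux = 2),
  rx("ssar2", "SSA_hydrate + H2 -> 4HB + H2O", -24.0, cpt = TRUE, flux = 2,
     red = c("NAD", "NADP")),
  rx("hbk", "4HB -> 4HBP", 20.0, slp = -1, flux = 2),
  rx("hbt", "4HBP + CoA -> 4HBCoA", -10.0, flux = 2),
  rx("hbd_a2", "4HBCoA -> vinylacetylCoA + H2O", 10.0, flux = 2),
  rx("hbd_b2", "vinylacetylCoA -> crotonylCoA", -10.0, flux = 2)
)

message("CETCH cycle (tartronate semialdehyde route)")
build_fixture(
  "cetch_ts", "CETCH cycle (tartronate semialdehyde route)",
  "aerobic", c(cetch_core, ts_block),
  "glycerate", GLYC, -80.6,
  list(slp_cost = 5, variants = 16, reactions = 20),
  dg_balance = c("ccr", "ssr", "ssar2", "msd"), pad_balance = "tsa_s")

message("CETCH cycle (glyoxylate shunt route)")
build_fixture(
  "cetch_gs", "CETCH cycle (glyoxylate shunt route)",
  "aerobic", c(cetch_core, gs_block),
  "pyruvate", PYR, -113.6,
  list(slp_cost = 6, variants = 144, reactions = 23),
  dg_balance = c("ccr", "ssr", "ssar2", "msd", "gr1", "gr3"),
  pad_balance = "gs_me")

message("All fixtures written and verified.")
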