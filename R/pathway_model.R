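#' @useDynLib doepath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical orderings used everywhere in the package.
PATHWAY_SPECIES <- c("TYR", "CUA", "CAA", "FEA", "CUCOA", "CACOA", "FECOA",
                     "DCUCOA", "DFECOA", "BDC", "DMC", "CUR")
PATHWAY_ENZYMES <- c("TAL", "C3H", "COMT", "FCS", "CCOAOMT", "DCS", "CURS")

# Carbon accounting: each cinnamate-derived unit counts once; the three
# curcuminoids are condensation products of two units.
CARBON_WEIGHTS <- c(TYR = 1, CUA = 1, CAA = 1, FEA = 1, CUCOA = 1, CACOA = 1,
                    FECOA = 1, DCUCOA = 1, DFECOA = 1, BDC = 2, DMC = 2, CUR = 2)

RATE_LAWS <- c("michaelis_menten", "mass_action", "mm_competitive",
               "mm_bisubstrate_competitive")

#' Construct a pathway reaction
#'
#' A reaction is an enzyme-catalysed conversion with one of four rate laws:
#' irreversible Michaelis-Menten, enzyme-proportional mass action,
#' single-substrate Michaelis-Menten with competitive inhibition by a pool of
#' species sharing the active site, or the bisubstrate competitive form used
#' for the condensation reactions. All fluxes are proportional to the enzyme
#' concentration.
#'
#' @param id Reaction label.
#' @param substrates Named numeric vector of substrate stoichiometries.
#' @param products Named numeric vector of product stoichiometries.
#' @param enzyme One of the seven pathway enzyme names.
#' @param rate_law One of `"michaelis_menten"`, `"mass_action"`,
#'   `"mm_competitive"`, `"mm_bisubstrate_competitive"`.
#' @param params Named list of kinetic parameters. `kcat` (1/h) and per-substrate
#'   `Km` values (mM) for Michaelis-Menten forms; `k` (1/(mM h)) for mass action.
#' @param competitor_pool Named numeric vector of Km values (mM) for the species
#'   competing for the enzyme's active site; empty unless the rate law is
#'   competitive.
#' @return An object of class `pathway_reaction`.
#' @export
reaction <- function(id, substrates, products, enzyme, rate_law, params,
                     competitor_pool = numeric()) {
  rate_law <- match.arg(rate_law, RATE_LAWS)
  stopifnot(is.character(id), length(id) == 1L,
            length(substrates) >= 1L, !is.null(names(substrates)),
            !is.null(names(products)))
  if (!all(unlist(params) > 0)) {
    stop("all kinetic parameters must be strictly positive in reaction ", id)
  }
  competitive <- rate_law %in% c("mm_competitive", "mm_bisubstrate_competitive")
  if (competitive && length(competitor_pool) == 0L) {
    stop("competitive rate law requires a non-empty competitor_pool: ", id)
  }
  if (!competitive && length(competitor_pool) > 0L) {
    stop("competitor_pool given for non-competitive rate law: ", id)
  }
  structure(list(id = id, substrates = substrates, products = products,
                 enzyme = enzyme, rate_law = rate_law, params = params,
                 competitor_pool = competitor_pool),
            class = "pathway_reaction")
}

#' Construct a pathway model
#'
#' Bundles the reaction network with enzyme concentrations, initial state and
#' simulation settings. Strain libraries are simulated by scaling each enzyme's
#' concentration: coded level -1 is the default concentration, +1 is
#' `high_level_multiplier` times the default.
#'
#' @param reactions List of [reaction()] objects.
#' @param default_enzyme_conc Named numeric vector (mM), one entry per enzyme.
#' @param initial_state Named numeric vector of initial concentrations (mM);
#'   species not named start at 0.
#' @param sim_horizon Batch simulation end point (h).
#' @param high_level_multiplier Fold-change between low and high coded levels.
#' @param rtol,atol ODE solver tolerances.
#' @param metadata Free-form list recorded with the model (e.g. calibration
#'   provenance).
#' @return An object of class `pathway_model`.
#' @export
pathway_model <- function(reactions, default_enzyme_conc, initial_state,
                          sim_horizon, high_level_multiplier = 5,
                          rtol = 1e-8, atol = 1e-10, metadata = list()) {
  stopifnot(length(default_enzyme_conc) == 7L,
            setequal(names(default_enzyme_conc), PATHWAY_ENZYMES),
            all(default_enzyme_conc > 0),
            high_level_multiplier > 0, sim_horizon > 0)
  enz <- vapply(reactions, function(r) r$enzyme, character(1))
  if (!all(enz %in% PATHWAY_ENZYMES)) {
    stop("unknown enzyme(s): ", paste(setdiff(enz, PATHWAY_ENZYMES), collapse = ", "))
  }
  species <- PATHWAY_SPECIES
  used <- unique(unlist(lapply(reactions, function(r)
    c(names(r$substrates), names(r$products), names(r$competitor_pool)))))
  if (!all(used %in% species)) {
    stop("unknown species: ", paste(setdiff(used, species), collapse = ", "))
  }
  y0 <- stats::setNames(numeric(length(species)), species)
  y0[names(initial_state)] <- initial_state
  model <- structure(
    list(species = species,
         enzymes = PATHWAY_ENZYMES,
         reactions = reactions,
         default_enzyme_conc = default_enzyme_conc[PATHWAY_ENZYMES],
         high_level_multiplier = high_level_multiplier,
         initial_state = y0,
         sim_horizon = sim_horizon,
         rtol = rtol, atol = atol,
         metadata = metadata),
    class = "pathway_model")
  model$encoding <- encode_network(model)
  model
}

# Flatten the reaction list into the parallel-array form consumed by the C++
# kernel. Done once at construction time.
encode_network <- function(model) {
  rx <- model$reactions
  nr <- length(rx)
  ns <- length(model$species)
  sp_idx <- function(nm) match(nm, model$species) - 1L
  type_code <- c(michaelis_menten = 0L, mass_action = 1L,
                 mm_competitive = 2L, mm_bisubstrate_competitive = 3L)

  r_type <- integer(nr); r_enz <- integer(nr)
  r_sub1 <- integer(nr); r_sub2 <- integer(nr)
  r_k <- numeric(nr); r_km1 <- numeric(nr); r_km2 <- numeric(nr)
  pool_sp <- integer(0); pool_km <- numeric(0); pool_start <- integer(nr + 1L)
  stoich <- matrix(0, ns, nr, dimnames = list(model$species, NULL))

  for (i in seq_len(nr)) {
    r <- rx[[i]]
    r_type[i] <- type_code[[r$rate_law]]
    r_enz[i] <- match(r$enzyme, model$enzymes) - 1L
    subs <- names(r$substrates)
    r_sub1[i] <- sp_idx(subs[1])
    r_sub2[i] <- if (length(subs) >= 2) sp_idx(subs[2]) else -1L
    if (r$rate_law == "mass_action") {
      r_k[i] <- r$params$k; r_km1[i] <- 1; r_km2[i] <- 1
    } else {
      r_k[i] <- r$params$kcat
      r_km1[i] <- r$params$Km[[subs[1]]]
      r_km2[i] <- if (length(subs) >= 2) r$params$Km[[subs[2]]] else 1
    }
    pool_start[i] <- length(pool_sp)
    if (length(r$competitor_pool)) {
      pool_sp <- c(pool_sp, sp_idx(names(r$competitor_pool)))
      pool_km <- c(pool_km, unname(r$competitor_pool))
    }
    stoich[names(r$substrates), i] <- stoich[names(r$substrates), i] - r$substrates
    stoich[names(r$products), i] <- stoich[names(r$products), i] + r$products
  }
  pool_start[nr + 1L] <- length(pool_sp)
  list(r_type = r_type, r_enz = r_enz, r_sub1 = r_sub1, r_sub2 = r_sub2,
       r_k = r_k, r_km1 = r_km1, r_km2 = r_km2,
       pool_start = pool_start, pool_sp = pool_sp, pool_km = pool_km,
       stoich = stoich)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("Pathway model:", length(x$species), "species,",
      length(x$reactions), "reactions,", length(x$enzymes), "enzymes\n")
  cat("  enzymes:", paste(x$enzymes, collapse = ", "), "\n")
  cat("  levels: low = default conc, high =", x$high_level_multiplier,
      "x default\n")
  cat("  batch horizon:", x$sim_horizon, "h; TYR0 =",
      x$initial_state[["TYR"]], "mM\n")
  invisible(x)
}

#' Enzyme concentrations for a coded strain
#'
#' Decodes a vector of coded levels (-1 low, +1 high) into enzyme
#' concentrations: `default * multiplier^((level + 1) / 2)`.
#'
#' @param model A [pathway_model()].
#' @param levels Numeric vector of 7 coded levels in \{-1, +1\}, ordered as
#'   `model$enzymes`.
#' @return Named numeric vector of enzyme concentrations (mM).
#' @export
decode_levels <- function(model, levels) {
  levels <- validate_strain_levels(levels)
  model$default_enzyme_conc * model$high_level_multiplier ^ ((levels + 1) / 2)
}

validate_strain_levels <- function(levels) {
  levels <- as.numeric(levels)
  if (length(levels) != 7L || !all(levels %in% c(-1, 1))) {
    stop("strain levels must be 7 coded values in {-1, +1}")
  }
  levels
}

#' The shipped curcuminoid pathway model
#'
#' Builds the twelve-species, thirteen-reaction network of the curcuminoid
#' pathway: TAL deaminates tyrosine to p-coumaric acid; C3H hydroxylates it to
#' caffeic acid (mass action); COMT methylates caffeic to ferulic acid; the
#' promiscuous CoA ligase FCS activates p-coumaric, caffeic and ferulic acid
#' (shared active site, competitive); CCOAOMT methylates caffeoyl-CoA to
#' feruloyl-CoA; the promiscuous DCS extends coumaroyl- and feruloyl-CoA to
#' their diketides; and the promiscuous CURS condenses one CoA ester with one
#' diketide into bisdemethoxycurcumin, demethoxycurcumin or curcumin.
#' Demethoxycurcumin arises from both mixed condensations.
#'
#' The kinetic parameters are not taken from literature; they are the output of
#' [calibrate_default_parameters()], chosen so that the noiseless full
#' factorial library has the qualitative structure used throughout the
#' package: the two top producers combine high C3H, DCS and CURS with low
#' FCS, COMT and CCOAOMT and are indifferent to TAL; TAL's main effect is not
#' significant; and C3H carries the largest absolute main effect. The
#' calibration provenance is stored in `$metadata`.
#'
#' @param params Optional named numeric vector overriding individual kinetic
#'   parameters; names as in [default_kinetic_parameters()].
#' @return A [pathway_model()].
#' @export
#' @examples
#' m <- build_default_model()
#' length(m$species)
build_default_model <- function(params = default_kinetic_parameters()) {
  p <- default_kinetic_parameters()
  if (!all(names(params) %in% names(p))) {
    stop("unknown parameter(s): ",
         paste(setdiff(names(params), names(p)), collapse = ", "))
  }
  p[names(params)] <- params

  fcs_pool <- c(CUA = p[["FCS.Km.CUA"]], CAA = p[["FCS.Km.CAA"]],
                FEA = p[["FCS.Km.FEA"]])
  dcs_pool <- c(CUCOA = p[["DCS.Km.CUCOA"]], FECOA = p[["DCS.Km.FECOA"]])
  curs_pool <- c(CUCOA = p[["CURS.Km.CUCOA"]], FECOA = p[["CURS.Km.FECOA"]],
                 DCUCOA = p[["CURS.Km.DCUCOA"]], DFECOA = p[["CURS.Km.DFECOA"]])
  curs_rx <- function(id, a, b, prod, kcat) {
    reaction(id, stats::setNames(c(1, 1), c(a, b)),
             stats::setNames(1, prod), "CURS", "mm_bisubstrate_competitive",
             list(kcat = kcat, Km = as.list(curs_pool[c(a, b)])),
             competitor_pool = curs_pool)
  }

  reactions <- list(
    reaction("TAL", c(TYR = 1), c(CUA = 1), "TAL", "michaelis_menten",
             list(kcat = p[["TAL.kcat"]], Km = list(TYR = p[["TAL.Km.TYR"]]))),
    reaction("C3H", c(CUA = 1), c(CAA = 1), "C3H", "mass_action",
             list(k = p[["C3H.k"]])),
    reaction("COMT", c(CAA = 1), c(FEA = 1), "COMT", "michaelis_menten",
             list(kcat = p[["COMT.kcat"]], Km = list(CAA = p[["COMT.Km.CAA"]]))),
    reaction("FCS_CUA", c(CUA = 1), c(CUCOA = 1), "FCS", "mm_competitive",
             list(kcat = p[["FCS.kcat"]], Km = list(CUA = p[["FCS.Km.CUA"]])),
             competitor_pool = fcs_pool),
    reaction("FCS_CAA", c(CAA = 1), c(CACOA = 1), "FCS", "mm_competitive",
             list(kcat = p[["FCS.kcat"]], Km = list(CAA = p[["FCS.Km.CAA"]])),
             competitor_pool = fcs_pool),
    reaction("FCS_FEA", c(FEA = 1), c(FECOA = 1), "FCS", "mm_competitive",
             list(kcat = p[["FCS.kcat"]], Km = list(FEA = p[["FCS.Km.FEA"]])),
             competitor_pool = fcs_pool),
    reaction("CCOAOMT", c(CACOA = 1), c(FECOA = 1), "CCOAOMT",
             "michaelis_menten",
             list(kcat = p[["CCOAOMT.kcat"]],
                  Km = list(CACOA = p[["CCOAOMT.Km.CACOA"]]))),
    reaction("DCS_CUCOA", c(CUCOA = 1), c(DCUCOA = 1), "DCS", "mm_competitive",
             list(kcat = p[["DCS.kcat"]],
                  Km = list(CUCOA = p[["DCS.Km.CUCOA"]])),
             competitor_pool = dcs_pool),
    reaction("DCS_FECOA", c(FECOA = 1), c(DFECOA = 1), "DCS", "mm_competitive",
             list(kcat = p[["DCS.kcat"]],
                  Km = list(FECOA = p[["DCS.Km.FECOA"]])),
             competitor_pool = dcs_pool),
    curs_rx("CURS_BDC", "CUCOA", "DCUCOA", "BDC", p[["CURS.kcat.BDC"]]),
    curs_rx("CURS_DMC1", "CUCOA", "DFECOA", "DMC", p[["CURS.kcat.DMC"]]),
    curs_rx("CURS_DMC2", "FECOA", "DCUCOA", "DMC", p[["CURS.kcat.DMC"]]),
    curs_rx("CURS_CUR", "FECOA", "DFECOA", "CUR", p[["CURS.kcat.CUR"]]))

  pathway_model(
    reactions,
    default_enzyme_conc = stats::setNames(rep(p[["enzyme.default_conc"]], 7),
                                          PATHWAY_ENZYMES),
    initial_state = c(TYR = p[["init.TYR"]]),
    sim_horizon = p[["sim.horizon"]],
    high_level_multiplier = 5,
    metadata = list(parameter_source = "calibrated",
                    calibration_seed = attr(default_kinetic_parameters(),
                                            "calibration_seed")))
}
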