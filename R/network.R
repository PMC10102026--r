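## Construction of the three-compartment mass-action transport network.
##
## The network reconstructs the canonical importin-alpha/beta import module,
## the CAS (CSE1L) importin-alpha recycling module, the CRM1/RanBP3 export
## module and the Ran GTPase cycle (RCC1 nucleotide exchange confined to the
## nucleus; RanGAP/RanBP1-stimulated hydrolysis confined to the cytoplasm;
## NTF2-mediated RanGDP import). Carrier-containing complexes shuttle through
## an explicit pore compartment by first-order translocation steps whose
## capacity scales with the pore count. All abundances and rate constants are
## exposed in a single editable configuration so that alternative
## parameterizations can be dropped in verbatim; the shipped defaults are a
## reconstructed parameterization, not fitted values.

.CARRIER_FAMILIES <- c("impb", "cas", "crm1", "ntf2", "ranbp3")

#' Default model configuration
#'
#' Returns the full editable configuration of the base transport model:
#' compartment volumes, initial species abundances (uM), rate constants and
#' the pore configuration. Abundances are micromolar free-protein
#' concentrations at t = 0 (all complexes start at zero; total Ran starts as
#' cytoplasmic RanGDP). Volumes follow the HeLa-like convention of a
#' cytoplasm several-fold larger than the nucleus. Pore capacity is expressed
#' as pores per cell relative to a 4000-pore reference.
#'
#' @return a list with elements \code{compartments}, \code{abundances},
#'   \code{rates}, \code{pores}, suitable for [buildNetwork()].
#' @examples
#' cfg <- baseModelConfig()
#' names(cfg)
#' @export
baseModelConfig <- function() {
  list(
    compartments = data.frame(
      name = c("cytoplasm", "nucleus", "pore"),
      volume = c(1200, 300, 30)  # fL
    ),
    abundances = data.frame(
      name        = c("RanGDP", "NTF2", "RCC1", "RanGAP", "RanBP1",
                      "RanBP3", "Impa", "Impb", "CAS", "CRM1"),
      compartment = c("cytoplasm", "cytoplasm", "nucleus", "cytoplasm",
                      "cytoplasm", "nucleus", "cytoplasm", "cytoplasm",
                      "cytoplasm", "cytoplasm"),
      conc        = c(15, 6, 1, 0.5, 2, 0.1, 4, 3, 3, 1)
    ),
    rates = c(
      # importin dimerization and Ran loading
      k_ab_on = 0.5,  k_ab_off = 0.005,     # Impa + Impb (KD 10 nM)
      k_bR_on = 5,    k_bR_off = 0.005,     # Impb + RanGTP (KD 1 nM)
      k_abR   = 5,                          # RanGTP-driven dimer disassembly
      # CAS / importin-alpha recycling
      k_cR_on = 5,    k_cR_off = 0.05,      # CAS + RanGTP
      k_cRa_on = 10,  k_cRa_off = 0.05,     # CAS:RanGTP + Impa
      k_ca_on = 1,    k_ca_off = 0.5,       # CAS + Impa (weak, RanGTP-free)
      k_caR_on = 2,   k_caR_off = 0.05,     # CAS:Impa + RanGTP
      # CRM1 / RanBP3 export
      k_xR_on = 2,    k_xR_off = 0.1,       # CRM1 + RanGTP
      k_xb3_on = 5,   k_xb3_off = 0.05,     # CRM1 + RanBP3
      k_xb3R_on = 5,  k_xb3R_off = 0.05,    # CRM1:RanBP3 + RanGTP
      # NTF2 shuttling of RanGDP
      k_nR_on = 5,    k_nR_off = 2,
      # Ran cycle enzymes
      k_rcc1 = 20,                          # nucleotide exchange (nucleus)
      k_gap = 0.5,                          # RanGAP on free RanGTP
      k_b1_on = 5,    k_b1_off = 0.05,      # RanBP1 + RanGTP
      k_gap_b1 = 20,                        # RanBP1-stimulated hydrolysis
      k_strip = 10,                         # RanBP1 stripping of carriers
      # cargo binding (k_off is derived from each cargo's KD)
      k_cargo_on = 1,
      # passive pore permeability of free cargo (s^-1); reporter-sized
      # cargo leaks slowly through pores against the active pump
      k_cargo_passive = 0.1,
      # pore translocation (NTF2 shuttles fast; CAS recycles quickly;
      # cargo-free importin-beta crosses slowly, limiting its futile
      # RanGTP-consuming cycle)
      k_pore_in = 1, k_pore_in_ntf2 = 10, k_pore_in_cas = 3,
      k_pore_in_Impb = 0.1, k_pore_out = 50
    ),
    pores = list(classes = list(
      list(count = 4000, selects = "all")
    ), reference_count = 4000)
  )
}

.composition <- function(name) {
  # species names are dot-joined moiety tokens; RanGTP/RanGDP carry one Ran
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  parts[parts %in% c("RanGTP", "RanGDP")] <- "Ran"
  tab <- table(parts)
  setNames(as.integer(tab), names(tab))
}

.carrierOf <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if ("Impb" %in% parts) return("impb")
  if ("CAS" %in% parts) return("cas")
  if ("CRM1" %in% parts) return("crm1")
  if ("NTF2" %in% parts) return("ntf2")
  if ("RanBP3" %in% parts) return("ranbp3")
  NA_character_
}

## table of molecular entities and the compartments they may occupy;
## translocating entities (carrier-containing) additionally occupy the pore
.baseEntities <- function() {
  ent <- function(name, comps, transloc = FALSE)
    list(name = name, comps = comps, transloc = transloc)
  cn <- c("cytoplasm", "nucleus")
  cnp <- c("cytoplasm", "nucleus", "pore")
  list(
    ent("RanGTP", cn), ent("RanGDP", cn),
    ent("NTF2", cnp, TRUE), ent("NTF2.RanGDP", cnp, TRUE),
    ent("RCC1", "nucleus"), ent("RanGAP", "cytoplasm"),
    ent("RanBP1", "cytoplasm"), ent("RanBP1.RanGTP", "cytoplasm"),
    ent("RanBP3", cnp, TRUE),
    ent("Impa", cn), ent("Impb", cnp, TRUE),
    ent("Impa.Impb", cnp, TRUE), ent("Impb.RanGTP", cnp, TRUE),
    ent("CAS", cnp, TRUE), ent("CAS.RanGTP", cnp, TRUE),
    ent("CAS.RanGTP.Impa", cnp, TRUE), ent("CAS.Impa", cnp, TRUE),
    ent("CRM1", cnp, TRUE), ent("CRM1.RanGTP", cnp, TRUE),
    ent("CRM1.RanBP3", cnp, TRUE), ent("CRM1.RanBP3.RanGTP", cnp, TRUE)
  )
}

## base reaction topology; each row: reactants, products, rate name(s),
## compartments where the reaction is instantiated ("both" = cytoplasm and
## nucleus), reversible flag
.baseReactionTable <- function() {
  r <- function(react, prod, kf, kr = NA, where = "both")
    list(react = react, prod = prod, kf = kf, kr = kr, where = where)
  list(
    r(c("Impa", "Impb"), "Impa.Impb", "k_ab_on", "k_ab_off"),
    r(c("Impb", "RanGTP"), "Impb.RanGTP", "k_bR_on", "k_bR_off"),
    r(c("Impa.Impb", "RanGTP"), c("Impb.RanGTP", "Impa"), "k_abR"),
    r(c("CAS", "RanGTP"), "CAS.RanGTP", "k_cR_on", "k_cR_off"),
    r(c("CAS.RanGTP", "Impa"), "CAS.RanGTP.Impa", "k_cRa_on", "k_cRa_off"),
    r(c("CAS", "Impa"), "CAS.Impa", "k_ca_on", "k_ca_off"),
    r(c("CAS.Impa", "RanGTP"), "CAS.RanGTP.Impa", "k_caR_on", "k_caR_off"),
    r(c("CRM1", "RanGTP"), "CRM1.RanGTP", "k_xR_on", "k_xR_off"),
    r(c("CRM1", "RanBP3"), "CRM1.RanBP3", "k_xb3_on", "k_xb3_off"),
    r(c("CRM1.RanBP3", "RanGTP"), "CRM1.RanBP3.RanGTP", "k_xb3R_on", "k_xb3R_off"),
    r(c("NTF2", "RanGDP"), "NTF2.RanGDP", "k_nR_on", "k_nR_off"),
    r(c("RanGDP", "RCC1"), c("RanGTP", "RCC1"), "k_rcc1", where = "nucleus"),
    r(c("RanGTP", "RanGAP"), c("RanGDP", "RanGAP"), "k_gap", where = "cytoplasm"),
    r(c("RanBP1", "RanGTP"), "RanBP1.RanGTP", "k_b1_on", "k_b1_off",
      where = "cytoplasm"),
    r(c("RanBP1.RanGTP", "RanGAP"), c("RanBP1", "RanGDP", "RanGAP"),
      "k_gap_b1", where = "cytoplasm"),
    r(c("Impb.RanGTP", "RanBP1"), c("Impb", "RanBP1.RanGTP"), "k_strip",
      where = "cytoplasm"),
    r(c("CAS.RanGTP", "RanBP1"), c("CAS", "RanBP1.RanGTP"), "k_strip",
      where = "cytoplasm"),
    r(c("CAS.RanGTP.Impa", "RanBP1"), c("CAS", "Impa", "RanBP1.RanGTP"),
      "k_strip", where = "cytoplasm"),
    r(c("CRM1.RanGTP", "RanBP1"), c("CRM1", "RanBP1.RanGTP"), "k_strip",
      where = "cytoplasm"),
    r(c("CRM1.RanBP3.RanGTP", "RanBP1"), c("CRM1", "RanBP3", "RanBP1.RanGTP"),
      "k_strip", where = "cytoplasm")
  )
}

.stateKey <- function(name, comp) paste0(name, "@", comp)

## instantiate a reaction list into indexed DataFrame rows against a species
## table; returns list of rows (reactants, products, rate name, k, comp)
.instantiateReactions <- function(rxTable, speciesDF, rates) {
  lookup <- setNames(seq_len(nrow(speciesDF)),
                     .stateKey(speciesDF$name, speciesDF$compartment))
  rows <- list()
  for (rx in rxTable) {
    comps <- if (identical(rx$where, "both")) c("cytoplasm", "nucleus") else rx$where
    for (cmp in comps) {
      rkeys <- .stateKey(rx$react, cmp)
      pkeys <- .stateKey(rx$prod, cmp)
      if (!all(c(rkeys, pkeys) %in% names(lookup))) next
      if (!rx$kf %in% names(rates))
        stop("missing rate constant: ", rx$kf)
      rows[[length(rows) + 1L]] <- list(
        reactants = unname(lookup[rkeys]), products = unname(lookup[pkeys]),
        rate = rx$kf, k = unname(rates[[rx$kf]]), compartment = cmp)
      if (!is.na(rx$kr)) {
        if (!rx$kr %in% names(rates))
          stop("missing rate constant: ", rx$kr)
        rows[[length(rows) + 1L]] <- list(
          reactants = unname(lookup[pkeys]), products = unname(lookup[rkeys]),
          rate = rx$kr, k = unname(rates[[rx$kr]]), compartment = cmp)
      }
    }
  }
  rows
}

## pore translocation steps for one translocating entity:
## cytoplasm -> pore, pore -> cytoplasm, nucleus -> pore, pore -> nucleus
.poreReactions <- function(name, speciesDF, rates, pores,
                           inRate = "k_pore_in", selective = TRUE) {
  lookup <- setNames(seq_len(nrow(speciesDF)),
                     .stateKey(speciesDF$name, speciesDF$compartment))
  fam <- .carrierOf(name)
  refN <- pores$reference_count %||% 4000
  capacity <- 0
  for (cl in pores$classes) {
    sel <- cl$selects
    if (length(sel) == 0) stop("pore class with empty selectivity")
    admits <- !selective || identical(sel, "all") || "all" %in% sel ||
      (!is.na(fam) && fam %in% sel)
    if (admits) capacity <- capacity + cl$count / refN
  }
  if (capacity <= 0) return(list())
  # translocation overrides, most specific first: per-entity (e.g. the
  # futile shuttling of empty importin-beta), then per carrier family
  # (e.g. the small NTF2 dimer shuttles much faster than karyopherins)
  entRate <- paste0(inRate, "_", name)
  famRate <- paste0(inRate, "_", fam)
  if (entRate %in% names(rates)) inRate <- entRate
  else if (!is.na(fam) && famRate %in% names(rates)) inRate <- famRate
  kin <- rates[[inRate]] * capacity
  kout <- rates[["k_pore_out"]] * capacity
  mk <- function(from, to, k, nm) list(
    reactants = unname(lookup[.stateKey(name, from)]),
    products = unname(lookup[.stateKey(name, to)]),
    rate = nm, k = k, compartment = "pore")
  list(mk("cytoplasm", "pore", kin, inRate),
       mk("nucleus", "pore", kin, inRate),
       mk("pore", "cytoplasm", kout, "k_pore_out"),
       mk("pore", "nucleus", kout, "k_pore_out"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assembleNetwork <- function(speciesDF, rxRows, compartments, pores, rates,
                             cargoes) {
  rx <- S4Vectors::DataFrame(
    reactants = IRanges::IntegerList(lapply(rxRows, `[[`, "reactants")),
    products = IRanges::IntegerList(lapply(rxRows, `[[`, "products")),
    rate = vapply(rxRows, `[[`, "", "rate"),
    k = vapply(rxRows, `[[`, 0, "k"),
    compartment = vapply(rxRows, `[[`, "", "compartment"))
  new("ReactionNetwork", species = speciesDF, reactions = rx,
      compartments = compartments, pores = pores, rates = rates,
      cargoes = cargoes)
}

#' Build the base transport network
#'
#' Assembles the three-compartment mass-action network from a configuration
#' of species abundances, rate constants and pore classes. The network
#' contains the importin-alpha/beta import module, CAS-mediated
#' importin-alpha recycling, the CRM1/RanBP3 export module and the Ran cycle
#' (RCC1 exchange in the nucleus, RanGAP/RanBP1 hydrolysis in the cytoplasm,
#' NTF2-mediated RanGDP import). Every rate constant must be present in the
#' configuration; a missing rate is an error, never a silent default.
#'
#' @param config a configuration list as returned by [baseModelConfig()] or
#'   [readModelConfig()]. Individual elements (e.g. a modified abundance
#'   table) can be replaced before calling.
#' @return a \linkS4class{ReactionNetwork}.
#' @examples
#' net <- buildNetwork()
#' net
#' @export
buildNetwork <- function(config = baseModelConfig()) {
  ab <- config$abundances
  stopifnot(is.data.frame(ab), all(c("name", "compartment", "conc") %in% names(ab)))
  if (any(ab$conc < 0)) stop("negative concentration in abundances")
  rates <- config$rates
  if (any(rates < 0)) stop("negative rate constant")
  if ("Ran" %in% ab$name) {
    # total Ran supplied: place it as cytoplasmic RanGDP
    i <- match("Ran", ab$name)
    ab$name[i] <- "RanGDP"; ab$compartment[i] <- "cytoplasm"
  }
  ents <- .baseEntities()
  known <- vapply(ents, `[[`, "", "name")
  bad <- setdiff(ab$name, known)
  if (length(bad)) stop("unknown species name: ", paste(bad, collapse = ", "))

  rows <- list()
  for (e in ents) for (cmp in e$comps) {
    init <- 0
    hit <- which(ab$name == e$name & ab$compartment == cmp)
    if (length(hit)) init <- sum(ab$conc[hit])
    rows[[length(rows) + 1L]] <- data.frame(
      name = e$name, compartment = cmp, init = init,
      carrier = .carrierOf(e$name), transloc = e$transloc,
      stringsAsFactors = FALSE)
  }
  spdf <- do.call(rbind, rows)
  # abundances placed in a compartment the species cannot occupy
  placed <- ab$conc > 0
  for (i in which(placed)) {
    if (!any(spdf$name == ab$name[i] & spdf$compartment == ab$compartment[i]))
      stop("species ", ab$name[i], " cannot occupy ", ab$compartment[i])
  }
  speciesDF <- S4Vectors::DataFrame(
    name = spdf$name, compartment = spdf$compartment, init = spdf$init,
    carrier = spdf$carrier, transloc = spdf$transloc)
  speciesDF$composition <- lapply(spdf$name, .composition)

  rxRows <- .instantiateReactions(.baseReactionTable(), speciesDF, rates)
  for (nm in unique(spdf$name[spdf$transloc]))
    rxRows <- c(rxRows, .poreReactions(nm, speciesDF, rates, config$pores))
  .assembleNetwork(speciesDF, rxRows, config$compartments, config$pores,
                   rates, list())
}

#' Cargo constructor
#'
#' @param name cargo name.
#' @param importMode "classical" (binds the importin-alpha:beta heterodimer)
#'   or "ibb" (binds importin-beta directly); "none" builds a cargo with no
#'   import pathway.
#' @param kdImport import dissociation constant in nM.
#' @param hasNes whether the cargo carries a nuclear export sequence.
#' @param kdExport export dissociation constant in nM (required with an NES).
#' @param totalConcentration total cargo concentration in uM (default 1, the
#'   dose used for reporter simulations).
#' @return a \linkS4class{CargoSpec}.
#' @examples
#' cargoSpec("NLS", "classical", kdImport = 32)
#' @export
cargoSpec <- function(name, importMode = c("classical", "ibb", "none"),
                      kdImport = 32, hasNes = FALSE, kdExport = NA_real_,
                      totalConcentration = 1,
                      passivePermeability = NA_real_) {
  importMode <- match.arg(importMode)
  if (importMode != "none" && (!is.finite(kdImport) || kdImport <= 0))
    stop("kdImport must be > 0")
  if (hasNes && (!is.finite(kdExport) || kdExport <= 0))
    stop("hasNes requires a positive kdExport")
  new("CargoSpec", name = name, importMode = importMode,
      kdImport = as.numeric(kdImport), hasNes = hasNes,
      kdExport = as.numeric(kdExport),
      totalConcentration = totalConcentration,
      passivePermeability = as.numeric(passivePermeability))
}

#' Add a cargo to a transport network
#'
#' Classical cargo gains reversible binding to the importin-alpha:beta
#' heterodimer; IBB cargo binds importin-beta directly. The association rate
#' is the configured \code{k_cargo_on} (default 1 uM^-1 s^-1) and the
#' dissociation rate is derived as KD * k_on. Nuclear RanGTP disassembles the
#' import complex, releasing free cargo. Cargo with an NES additionally binds
#' the CRM1:RanBP3:RanGTP export complex with its export KD; the exported
#' complex is disassembled in the cytoplasm by RanBP1 stripping. All
#' cargo-carrier complexes translocate through admissible pore classes.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param cargo a \linkS4class{CargoSpec}.
#' @return the extended \linkS4class{ReactionNetwork}.
#' @examples
#' net <- addCargo(buildNetwork(), cargoSpec("NLS", "classical", 32))
#' reactionCount(net)
#' @export
addCargo <- function(network, cargo) {
  stopifnot(is(network, "ReactionNetwork"), is(cargo, "CargoSpec"))
  validObject(cargo)
  if (cargo@name %in% vapply(network@cargoes, slot, "", "name"))
    stop("cargo name already in network: ", cargo@name)
  if (cargo@name %in% network@species$name)
    stop("cargo name collides with a species name: ", cargo@name)
  rates <- network@rates
  kon <- rates[["k_cargo_on"]]
  nm <- cargo@name
  cn <- c("cytoplasm", "nucleus")
  cnp <- c("cytoplasm", "nucleus", "pore")

  addState <- function(df, name, comps, init = 0, initComp = NULL,
                       transloc = FALSE) {
    for (cmp in comps) {
      df <- rbind(df, S4Vectors::DataFrame(
        name = name, compartment = cmp,
        init = if (!is.null(initComp) && cmp == initComp) init else 0,
        carrier = .carrierOf(name), transloc = transloc,
        composition = I(list(.composition(name)))))
    }
    df
  }
  sp <- network@species
  sp <- addState(sp, nm, cnp, init = cargo@totalConcentration,
                 initComp = "cytoplasm")
  newRx <- list()
  if (cargo@importMode == "classical") {
    sp <- addState(sp, paste0(nm, ".Impa.Impb"), cnp, transloc = TRUE)
    newRx <- c(newRx, list(
      list(react = c(nm, "Impa.Impb"), prod = paste0(nm, ".Impa.Impb"),
           kf = "k_cargo_on", kr = NA, where = "both"),
      list(react = c(paste0(nm, ".Impa.Impb"), "RanGTP"),
           prod = c("Impb.RanGTP", "Impa", nm), kf = "k_abR", kr = NA,
           where = "both")))
  } else if (cargo@importMode == "ibb") {
    sp <- addState(sp, paste0(nm, ".Impb"), cnp, transloc = TRUE)
    newRx <- c(newRx, list(
      list(react = c(nm, "Impb"), prod = paste0(nm, ".Impb"),
           kf = "k_cargo_on", kr = NA, where = "both"),
      list(react = c(paste0(nm, ".Impb"), "RanGTP"),
           prod = c("Impb.RanGTP", nm), kf = "k_abR", kr = NA,
           where = "both")))
  }
  if (cargo@hasNes) {
    sp <- addState(sp, paste0(nm, ".CRM1.RanBP3.RanGTP"), cnp, transloc = TRUE)
    newRx <- c(newRx, list(
      list(react = c(nm, "CRM1.RanBP3.RanGTP"),
           prod = paste0(nm, ".CRM1.RanBP3.RanGTP"),
           kf = "k_cargo_on", kr = NA, where = "both"),
      list(react = c(paste0(nm, ".CRM1.RanBP3.RanGTP"), "RanBP1"),
           prod = c(nm, "CRM1", "RanBP3", "RanBP1.RanGTP"),
           kf = "k_strip", kr = NA, where = "cytoplasm")))
  }
  # per-cargo dissociation constants enter as named off-rates
  kdImp <- cargo@kdImport / 1000  # nM -> uM
  rates[[paste0("k_off_", nm)]] <- kdImp * kon
  if (cargo@importMode != "none") {
    cplx <- if (cargo@importMode == "classical") paste0(nm, ".Impa.Impb")
            else paste0(nm, ".Impb")
    rsrc <- if (cargo@importMode == "classical") c(nm, "Impa.Impb")
            else c(nm, "Impb")
    newRx <- c(newRx, list(
      list(react = cplx, prod = rsrc, kf = paste0("k_off_", nm), kr = NA,
           where = "both")))
  }
  if (cargo@hasNes) {
    rates[[paste0("k_offx_", nm)]] <- (cargo@kdExport / 1000) * kon
    newRx <- c(newRx, list(
      list(react = paste0(nm, ".CRM1.RanBP3.RanGTP"),
           prod = c(nm, "CRM1.RanBP3.RanGTP"),
           kf = paste0("k_offx_", nm), kr = NA, where = "both")))
  }
  # per-cargo passive permeability override (e.g. large receptor
  # complexes diffuse through pores far more slowly than GFP-sized
  # reporters); entity-name override handled by .poreReactions
  if (!is.na(cargo@passivePermeability))
    rates[[paste0("k_cargo_passive_", nm)]] <- cargo@passivePermeability
  rxRows <- .instantiateReactions(newRx, sp, rates)
  cargoComplexes <- unique(sp$name[sp$transloc &
                                     startsWith(sp$name, paste0(nm, "."))])
  for (s in cargoComplexes)
    rxRows <- c(rxRows, .poreReactions(s, sp, rates, network@pores))
  # slow passive diffusion of free cargo through all pore classes
  rxRows <- c(rxRows, .poreReactions(nm, sp, rates, network@pores,
                                     inRate = "k_cargo_passive",
                                     selective = FALSE))

  # re-index existing reactions against the extended species table (indices
  # are stable because species are appended)
  oldRows <- lapply(seq_len(nrow(network@reactions)), function(i) list(
    reactants = as.integer(network@reactions$reactants[[i]]),
    products = as.integer(network@reactions$products[[i]]),
    rate = network@reactions$rate[i], k = network@reactions$k[i],
    compartment = network@reactions$compartment[i]))
  .assembleNetwork(sp, c(oldRows, rxRows), network@compartments,
                   network@pores, rates, c(network@cargoes, cargo))
}

#' @describeIn buildNetwork number of elementary reaction steps (each
#'   direction of a reversible reaction counts once).
#' @param network a ReactionNetwork.
#' @export
reactionCount <- function(network) nrow(network@reactions)

#' @describeIn buildNetwork species table (one row per
#'   species-in-compartment).
#' @export
networkSpecies <- function(network) network@species

#' @describeIn buildNetwork reaction table.
#' @export
networkReactions <- function(network) network@reactions

setMethod("show", "ReactionNetwork", function(object) {
  sp <- object@species
  cat("ReactionNetwork:", length(unique(sp$name)), "species over",
      nrow(sp), "compartmental states,", nrow(object@reactions),
      "elementary reactions\n")
  cat("  compartments:", paste(sprintf("%s (%g fL)",
      object@compartments$name, object@compartments$volume), collapse = ", "),
      "\n")
  cat("  pore classes:", length(object@pores$classes), "\n")
  if (length(object@cargoes))
    cat("  cargoes:", paste(vapply(object@cargoes, slot, "", "name"),
        collapse = ", "), "\n")
})

setMethod("show", "CargoSpec", function(object) {
  cat(sprintf("CargoSpec '%s': %s import (KD %g nM)%s, %g uM total\n",
      object@name, object@importMode, object@kdImport,
      if (object@hasNes) sprintf(", NES (KD %g nM)", object@kdExport) else "",
      object@totalConcentration))
})
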