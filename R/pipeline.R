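## Configuration loading, SBML export and the end-to-end pipeline driver
## tying the stages together (synthetic cohort -> heterogeneity screen ->
## frequency matching; transcript profiles -> model predictions ->
## stratified test; feedback switch analysis; morphometry). Each run emits
## a JSON manifest capturing the configuration hash, seeds and outputs so
## deterministic stages reproduce byte-identical results.

#' Read a model configuration from YAML
#'
#' The file may override any part of [baseModelConfig()]: an
#' \code{abundances} table (name/compartment/conc), a \code{rates} map, a
#' \code{compartments} table and a \code{pores} block. Omitted elements
#' keep their defaults; unknown rate names are an error.
#'
#' @param path YAML file path.
#' @return a configuration list for [buildNetwork()].
#' @export
readModelConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- baseModelConfig()
  if (!is.null(raw$compartments)) {
    cmp <- do.call(rbind, lapply(raw$compartments, as.data.frame))
    cfg$compartments <- cmp
  }
  if (!is.null(raw$abundances)) {
    ab <- do.call(rbind, lapply(raw$abundances, as.data.frame))
    for (i in seq_len(nrow(ab))) {
      hit <- cfg$abundances$name == ab$name[i]
      if (any(hit)) {
        cfg$abundances$conc[hit] <- ab$conc[i]
        if (!is.null(ab$compartment))
          cfg$abundances$compartment[hit] <- ab$compartment[i]
      } else {
        cfg$abundances <- rbind(cfg$abundances, ab[i, ])
      }
    }
  }
  if (!is.null(raw$rates)) {
    unknown <- setdiff(names(raw$rates), names(cfg$rates))
    if (length(unknown))
      stop("unknown rate constant(s) in config: ",
           paste(unknown, collapse = ", "))
    for (nm in names(raw$rates)) cfg$rates[[nm]] <- raw$rates[[nm]]
  }
  if (!is.null(raw$pores)) cfg$pores <- raw$pores
  cfg
}

#' Export a network as SBML Level 3
#'
#' Writes the species, compartments and mass-action reactions of a
#' \linkS4class{ReactionNetwork} as an SBML Level 3 Version 2 document for
#' cross-validation in external simulators. Kinetic laws are explicit
#' mass-action rate expressions in MathML.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportSBML <- function(network, path) {
  sp <- network@species
  rx <- network@reactions
  sid <- function(i) sprintf("s%d_%s_%s", i,
                             gsub("[^A-Za-z0-9]", "_", sp$name[i]),
                             substr(sp$compartment[i], 1, 2))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "transportModel")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (i in seq_len(nrow(network@compartments)))
    xml2::xml_add_child(lc, "compartment",
      id = network@compartments$name[i],
      size = as.character(network@compartments$volume[i]),
      constant = "true", spatialDimensions = "3")
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(sp)))
    xml2::xml_add_child(ls, "species", id = sid(i),
      name = paste0(sp$name[i], "@", sp$compartment[i]),
      compartment = sp$compartment[i],
      initialConcentration = as.character(sp$init[i]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  lp <- xml2::xml_add_child(model, "listOfParameters")
  seen <- character(0)
  for (j in seq_len(nrow(rx))) {
    if (rx$rate[j] %in% seen) next
    seen <- c(seen, rx$rate[j])
    xml2::xml_add_child(lp, "parameter", id = rx$rate[j],
      value = as.character(rx$k[j]), constant = "true")
  }
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(rx))) {
    re <- as.integer(rx$reactants[[j]])
    pr <- as.integer(rx$products[[j]])
    rnode <- xml2::xml_add_child(lr, "reaction",
      id = sprintf("r%03d", j), reversible = "false")
    lre <- xml2::xml_add_child(rnode, "listOfReactants")
    for (i in re) xml2::xml_add_child(lre, "speciesReference",
      species = sid(i), stoichiometry = "1", constant = "true")
    lpr <- xml2::xml_add_child(rnode, "listOfProducts")
    for (i in pr) xml2::xml_add_child(lpr, "speciesReference",
      species = sid(i), stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(rnode, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
      xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", rx$rate[j])
    for (i in re) xml2::xml_add_child(ap, "ci", sid(i))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in dependency order and writes CSV
#' outputs plus a JSON run manifest. Stages: \code{cohort} (synthetic
#' cohort, heterogeneity screen, frequency matching), \code{model}
#' (per-outgrowth transcript profiles, steady-state N/C predictions,
#' percentile-stratified tests), \code{switch} (feedback switch curves and
#' ultrasensitivity indices), \code{morphometry} (circularity, PLA spot
#' calling, N/C intensity recovery on generated fixtures). A partial
#' failure aborts with a stage-labelled error.
#'
#' @param config a list (or YAML file path) with elements \code{outdir},
#'   \code{seed}, \code{stages} (character subset of
#'   c("cohort","model","switch","morphometry")), and optional per-stage
#'   parameter blocks.
#' @return list of per-stage results (also written under \code{outdir});
#'   the manifest is \code{<outdir>/manifest.json}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("config$outdir is required")
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("cohort", "model", "switch", "morphometry")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character(0)
  stamp <- function(stage, f) {
    tryCatch(f, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(df, name) {
    p <- file.path(config$outdir, name)
    write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
  }

  if ("cohort" %in% stages) results$cohort <- stamp("cohort", {
    spec <- do.call(cohortSpec, c(config$cohort %||% list(),
                                  list(seed = seed)))
    se <- genExpressionCohort(spec)
    het <- heterogeneityScreen(se)
    calls <- frequencyMatch(se, genes = het$gene[het$flagged])
    emit(het, "heterogeneity.csv")
    emit(calls, "frequency_calls.csv")
    list(screen = het, calls = calls,
         truth = S4Vectors::metadata(se)$groundTruth$labels)
  })

  if ("model" %in% stages) results$model <- stamp("model", {
    net <- buildNetwork(config$model$config %||% baseModelConfig())
    prof <- genModelProfiles(config$model$n_outgrowths %||% 20,
                             config$model$dispersion %||% 0.3,
                             seed = seed)
    cargo <- cargoSpec("NLS2x", "classical", 2.5)
    nc <- apply(prof, 1, function(p) {
      ss <- steadyState(addCargo(
        suppressMessages(scaleInitialConditions(p, net)), cargo))
      if (ss@converged) ss@ncRatio[["NLS2x"]] else NA
    })
    tests <- lapply(c(KPNA = "Impa", KPNB1 = "Impb", CSE1L = "CAS"),
      function(spn) {
        strat <- switch(spn,
          Impa = rowMeans(prof[, paste0("KPNA", 1:7)]),
          Impb = prof[, "KPNB1"], CAS = prof[, "CSE1L"])
        alt <- if (spn == "CAS") "less" else "greater"
        stratifiedPredictionTest(nc, strat, alternative = alt)
      })
    df <- data.frame(outgrowth = rownames(prof), nc_ratio = nc, prof)
    emit(df, "model_predictions.csv")
    list(predictions = df, tests = tests)
  })

  if ("switch" %in% stages) results$switch <- stamp("switch", {
    net <- buildNetwork()
    folds <- config$switch$folds %||% 2^seq(-2, 2, length.out = 13)
    kds <- config$switch$kd %||% c(2.5, 32, 320)
    rows <- list()
    for (kd in kds) for (en in c(TRUE, FALSE)) {
      fm <- buildFeedbackModel(net, erbbCargo(kd),
                               config$switch$gainCas %||% 6,
                               config$switch$gainImpa %||% 0.8,
                               enabled = en)
      cv <- cnCurve(fm, folds)
      ui <- ultrasensitivityIndex(cv)
      rows[[length(rows) + 1L]] <- data.frame(
        kd = kd, feedback = en, fold = cv@folds, cn = cv@cnRatio,
        branch = cv@branch, converged = cv@converged,
        maxSlope = ui$maxSlope, width = ui$transitionWidth)
    }
    df <- do.call(rbind, rows)
    emit(df, "switch_curves.csv")
    df
  })

  if ("morphometry" %in% stages) results$morphometry <- stamp("morphometry", {
    gm <- genOutgrowthMasks(config$morphometry$n_masks %||% 12, seed = seed)
    circ <- do.call(rbind, lapply(seq_along(gm$masks), function(i) {
      cbind(mask = i, circularity(gm$masks[[i]]))
    }))
    pla <- genPlaImage(n_nuclei = config$morphometry$n_nuclei %||% 6,
                       outOfGate = 2, seed = seed)
    spots <- plaSpots(pla$photons, pla$nuclei)
    ncc <- genNcCells(n_cells = config$morphometry$n_cells %||% 9,
                      seed = seed)
    ncr <- ncIntensity(ncc$channel1, ncc$channel2, ncc$nuclearMask,
                       ncc$cellMask)
    emit(circ, "circularity.csv")
    emit(data.frame(nucleus = names(spots$countsPerNucleus),
                    spots = spots$countsPerNucleus), "pla_counts.csv")
    emit(ncr, "nc_ratios.csv")
    list(circularity = circ, pla = spots, nc = ncr,
         truth = list(masks = gm$groundTruth, pla = pla$groundTruth,
                      nc = ncc$groundTruth))
  })

  manifest <- list(
    package = "KaryoSwitch",
    version = as.character(utils::packageVersion("KaryoSwitch")),
    seed = seed, stages = stages,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
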