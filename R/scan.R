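## Perturbation analyses built on the steady-state solver: transcript-driven
## scaling of initial conditions, single-species sensitivity scans, and the
## percentile-stratified rank-sum comparison used to relate per-outgrowth
## transcript abundance to predicted transport capacity.

## gene -> model species map; KPNA1..KPNA7 aggregate onto the lumped Impa
.GENE_MAP <- c(
  KPNA1 = "Impa", KPNA2 = "Impa", KPNA3 = "Impa", KPNA4 = "Impa",
  KPNA5 = "Impa", KPNA6 = "Impa", KPNA7 = "Impa",
  KPNB1 = "Impb", CSE1L = "CAS", XPO1 = "CRM1", RAN = "Ran",
  RANBP1 = "RanBP1", RANBP3 = "RanBP3", RANGAP1 = "RanGAP",
  RCC1 = "RCC1", NUTF2 = "NTF2")

#' Scale model initial conditions from a transcript profile
#'
#' Maps relative transcript levels onto the transport proteins and scales
#' each protein's initial concentration multiplicatively (linear
#' transcript-to-protein scaling). KPNA1-7 aggregate onto the lumped
#' importin-alpha with equal isoform weights by default. Genes without a
#' mapping are ignored; mapped proteins absent from the profile stay at
#' their base values (noted in the returned attributes).
#'
#' @param profile named numeric vector of relative transcript levels
#'   (1 = base), names are gene symbols.
#' @param network the base \linkS4class{ReactionNetwork}.
#' @param isoformWeights optional named weights for the KPNA1-7 aggregation
#'   (default equal).
#' @return the rescaled network, with attribute \code{"missing"} listing
#'   mapped proteins that fell back to base values.
#' @examples
#' net <- buildNetwork()
#' net2 <- scaleInitialConditions(c(CSE1L = 2, KPNB1 = 0.8), net)
#' @export
scaleInitialConditions <- function(profile, network, isoformWeights = NULL) {
  stopifnot(is.numeric(profile), !is.null(names(profile)))
  if (any(profile <= 0)) stop("relative transcript levels must be > 0")
  mapped <- intersect(names(profile), names(.GENE_MAP))
  targets <- unique(unname(.GENE_MAP))
  folds <- setNames(rep(NA_real_, length(targets)), targets)
  # KPNA1-7: weighted mean of relative isoform levels
  kpna <- mapped[.GENE_MAP[mapped] == "Impa"]
  if (length(kpna)) {
    w <- if (is.null(isoformWeights)) rep(1, length(kpna)) else
      isoformWeights[kpna]
    folds["Impa"] <- sum(w * profile[kpna]) / sum(w)
  }
  for (g in mapped[.GENE_MAP[mapped] != "Impa"])
    folds[.GENE_MAP[[g]]] <- profile[[g]]
  missing <- names(folds)[is.na(folds)]
  if (length(missing))
    message("profile lacks ", paste(missing, collapse = ", "),
            "; corresponding proteins stay at base values")
  for (sp in names(folds)[!is.na(folds)])
    network <- scaleSpecies(network, sp, folds[[sp]])
  attr(network, "missing") <- missing
  network
}

#' Sensitivity of steady-state N/C ratios to one species' abundance
#'
#' Re-solves the steady state of the network over a grid of fold-changes in
#' the initial abundance of one species, for each supplied cargo. The
#' default grid spans 0.5x to 2x, the range of outgrowth-to-outgrowth
#' transcript variation the stratified analyses address.
#'
#' @param network base \linkS4class{ReactionNetwork} (no cargo).
#' @param species base protein name to scan (e.g. "CAS").
#' @param folds positive fold multipliers (default 9 log-spaced points,
#'   0.5-2x).
#' @param cargoes list of \linkS4class{CargoSpec} objects.
#' @return a data.frame with columns \code{cargo}, \code{fold},
#'   \code{nc_ratio}, \code{converged}.
#' @examples
#' \donttest{
#' sc <- sensitivityScan(buildNetwork(), "CAS", c(0.5, 1, 2),
#'                       list(cargoSpec("NLS", "classical", 32)))
#' }
#' @export
sensitivityScan <- function(network, species,
                            folds = 2^seq(-1, 1, length.out = 9),
                            cargoes) {
  if (any(folds <= 0)) stop("fold multipliers must be > 0")
  if (is(cargoes, "CargoSpec")) cargoes <- list(cargoes)
  out <- list()
  for (cg in cargoes) {
    prev <- NULL
    for (f in folds) {
      net <- addCargo(scaleSpecies(network, species, f), cg)
      ss <- steadyState(net, state = prev)
      if (ss@converged) prev <- ss@concentrations
      out[[length(out) + 1L]] <- data.frame(
        cargo = cg@name, fold = f,
        nc_ratio = if (length(ss@ncRatio)) unname(ss@ncRatio[cg@name]) else NA,
        converged = ss@converged)
    }
  }
  do.call(rbind, out)
}

#' Percentile-stratified one-sided rank-sum test
#'
#' Splits per-sample values at a percentile of a stratifying abundance
#' (default 65th, so the top ceiling(0.35 n) samples form the high group,
#' ties broken by stable sample order) and compares groups with a one-sided
#' Wilcoxon rank-sum test.
#'
#' @param values numeric, per-sample response (e.g. predicted N/C ratio).
#' @param stratifier numeric, per-sample abundance used for the split.
#' @param percentile split percentile (default 65).
#' @param alternative direction of the test for high vs low group
#'   ("greater": high-group values larger).
#' @return list with \code{medians} (high/low), \code{p.value},
#'   \code{direction}, \code{n} (group sizes).
#' @examples
#' stratifiedPredictionTest(1:20 + rnorm(20, 0, .1), 1:20)
#' @export
stratifiedPredictionTest <- function(values, stratifier, percentile = 65,
                                     alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values) == length(stratifier))
  if (length(unique(stratifier)) == 1L)
    stop("degenerate stratifier: all values tied")
  n <- length(values)
  nHigh <- ceiling((1 - percentile / 100) * n)
  ordIdx <- order(stratifier, seq_len(n), decreasing = TRUE)
  high <- sort(ordIdx[seq_len(nHigh)])
  grp <- rep("low", n); grp[high] <- "high"
  if (min(table(grp)) < 3) stop("fewer than 3 samples per group after split")
  wt <- wilcox.test(values[grp == "high"], values[grp == "low"],
                    alternative = alternative, exact = FALSE, correct = TRUE)
  list(medians = c(high = median(values[grp == "high"]),
                   low = median(values[grp == "low"])),
       p.value = unname(wt$p.value),
       direction = alternative,
       n = c(high = sum(grp == "high"), low = sum(grp == "low")))
}
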