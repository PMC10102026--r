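## Seeded synthetic-data generators emulating the statistical structure of
## the study's inputs: the single-outgrowth expression cohort (20 biological
## ten-cell outgrowths plus 16 pool-and-split equivalents per condition),
## labelled outgrowth masks for circularity analysis, photon-count PLA
## images, paired-channel cell images for N/C quantification, and
## per-outgrowth transcript profiles for model scaling. Every generator is
## a pure function of its specification and seed, and serializes its ground
## truth alongside the data. Distributional choices (lognormal noise,
## Gaussian spots, Poisson photons) are invented stand-ins; only the
## structural constants (20/16 samples, 35% penetrance, the 10% background
## rate, 100-400 um^2 gate, 5-photon threshold, 0.142 um pixels) follow the
## study design.

#' Cohort specification for the synthetic expression generator
#'
#' @param n_genes number of genes.
#' @param n_biological biological 10-cell outgrowth samples per condition.
#' @param n_poolsplit pool-and-split technical samples per condition.
#' @param frac_heterogeneous fraction of genes with AP-independent
#'   two-state heterogeneity among biological samples.
#' @param n_matched number of frequency-matched genes (high state tied to
#'   the treated condition).
#' @param p_high probability a treated outgrowth occupies the high state
#'   for a frequency-matched gene (the phenotype penetrance).
#' @param p_background probability an untreated outgrowth occupies the
#'   high state (the spontaneous background rate that motivates the
#'   10th/90th percentile thresholds).
#' @param high_fc log2 fold-change of the high state.
#' @param sd_bio,sd_tech biological / technical lognormal noise scales
#'   (log2 sd).
#' @param dropout per-value detection dropout rate.
#' @param seed integer seed.
#' @return a list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(n_genes = 1000, n_biological = 20, n_poolsplit = 16,
                       frac_heterogeneous = 0.05, n_matched = 30,
                       p_high = 0.35, p_background = 0.10, high_fc = 3,
                       sd_bio = 0.25, sd_tech = 0.2, dropout = 0.02,
                       seed = 1L) {
  stopifnot(p_high >= 0, p_high <= 1, p_background >= 0, p_background <= 1,
            sd_bio > 0, sd_tech > 0, frac_heterogeneous >= 0,
            frac_heterogeneous <= 1)
  if (n_matched + round(frac_heterogeneous * n_genes) > n_genes)
    stop("impossible spec: planted gene classes exceed n_genes")
  structure(as.list(environment()), class = "CohortSpec")
}

#' Generate a synthetic single-outgrowth expression cohort
#'
#' Gene classes: null genes share one lognormal distribution across all
#' samples; heterogeneous genes follow a two-state mixture (50% high) in
#' biological samples of both conditions; frequency-matched genes occupy
#' the high state with probability \code{p_high} per treated outgrowth and
#' \code{p_background} per untreated outgrowth. Pool-and-split samples
#' carry technical noise around the condition mean (mixtures averaged
#' out). Detection dropout is applied uniformly at random.
#'
#' @param spec a [cohortSpec()].
#' @return \code{SummarizedExperiment} with assays \code{exprs} (log2) and
#'   \code{detected}, colData (condition, sample_type) and the ground
#'   truth in \code{metadata()$groundTruth} (per-gene labels, per-sample
#'   high-state assignments).
#' @export
genExpressionCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  nG <- spec$n_genes
  nHet <- round(spec$frac_heterogeneous * nG)
  nFm <- spec$n_matched
  labels <- rep("null", nG)
  if (nHet > 0) labels[seq_len(nHet)] <- "heterogeneous"
  if (nFm > 0) labels[nHet + seq_len(nFm)] <- "frequency_matched"
  genes <- sprintf("gene%04d", seq_len(nG))
  base <- runif(nG, 6, 12)  # log2 baseline intensity

  conds <- c("minusAP", "plusAP")
  nB <- spec$n_biological; nP <- spec$n_poolsplit
  samples <- data.frame(
    sample = c(t(outer(conds, c(sprintf("bio%02d", seq_len(nB)),
                                sprintf("ps%02d", seq_len(nP))),
                       paste, sep = "_"))),
    condition = rep(conds, each = nB + nP),
    sample_type = rep(rep(c("biological", "poolsplit"), c(nB, nP)), 2))

  x <- matrix(NA_real_, nG, nrow(samples),
              dimnames = list(genes, samples$sample))
  highState <- matrix(FALSE, nG, nrow(samples),
                      dimnames = dimnames(x))
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    bio <- samples$condition == cond & samples$sample_type == "biological"
    ps <- samples$condition == cond & samples$sample_type == "poolsplit"
    pHigh <- ifelse(labels == "heterogeneous", 0.5,
             ifelse(labels == "frequency_matched",
                    if (cond == "plusAP") spec$p_high else spec$p_background,
                    0))
    hs <- matrix(rbinom(nG * nB, 1, rep(pHigh, nB)) == 1, nG, nB)
    highState[, bio] <- hs
    mu <- base + hs * spec$high_fc
    x[, bio] <- mu + matrix(rnorm(nG * nB, 0, spec$sd_bio), nG, nB)
    # pool-and-split: technical replicates of the pooled condition mean
    condMean <- base + pHigh * spec$high_fc
    x[, ps] <- condMean + matrix(rnorm(nG * nP, 0, spec$sd_tech), nG, nP)
  }
  detected <- matrix(runif(length(x)) >= spec$dropout, nG, ncol(x),
                     dimnames = dimnames(x))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = x, detected = detected),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample),
    rowData = S4Vectors::DataFrame(gene = genes, label = labels))
  S4Vectors::metadata(se)$groundTruth <- list(
    labels = setNames(labels, genes), highState = highState,
    spec = unclass(spec))
  se
}

## rasterize a union of discs into a label value on a canvas
.rasterDiscs <- function(canvas, centers, radii, value) {
  n <- nrow(canvas)
  m <- ncol(canvas)
  for (i in seq_along(radii)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; r <- radii[i]
    xr <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
    yr <- max(1, floor(cy - r)):min(m, ceiling(cy + r))
    sub <- outer(xr - cx, yr - cy, function(a, b) a^2 + b^2) <= r^2
    canvas[xr, yr][sub] <- value
  }
  canvas
}

## analytic area and perimeter of a union of discs with one central disc
## and lobes at distance d (pairwise intersections with the centre only)
.discUnionGeometry <- function(r0, lobes) {
  area <- pi * r0^2
  perim <- 2 * pi * r0
  for (lb in lobes) {
    r1 <- lb$r; d <- lb$d
    # circle-circle intersection
    if (d >= r0 + r1) { area <- area + pi * r1^2; perim <- perim + 2 * pi * r1; next }
    if (d <= abs(r0 - r1)) next  # fully contained
    a0 <- acos((d^2 + r0^2 - r1^2) / (2 * d * r0))  # half-angle hidden on centre
    a1 <- acos((d^2 + r1^2 - r0^2) / (2 * d * r1))  # half-angle hidden on lobe
    lens <- r0^2 * (a0 - sin(2 * a0) / 2) + r1^2 * (a1 - sin(2 * a1) / 2)
    area <- area + pi * r1^2 - lens
    # hide the arc inside the lobe on the centre circle; add the lobe's
    # visible arc
    perim <- perim - 2 * a0 * r0 + (2 * pi - 2 * a1) * r1
  }
  list(area = area, perimeter = perim)
}

#' Generate labelled outgrowth masks with known circularity
#'
#' Objects are discs (lobe count 1, true circularity 1) or unions of a
#' central disc with satellite lobes; the analytic area and perimeter of
#' the generating geometry (pairwise centre-lobe intersections) give the
#' target circularity recorded in the ground truth.
#'
#' @param n number of masks.
#' @param radiusRange central-disc radius range (px).
#' @param lobeCounts possible lobe counts, sampled uniformly.
#' @param pixelSize um per px.
#' @param seed integer seed.
#' @return list: \code{masks} (list of \linkS4class{LabelMask}, one object
#'   each), \code{groundTruth} data.frame (lobes, analytic area/perimeter
#'   in px units, true_circularity).
#' @export
genOutgrowthMasks <- function(n, radiusRange = c(25, 45),
                              lobeCounts = c(1, 3), pixelSize = 0.142,
                              seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  masks <- vector("list", n)
  gt <- list()
  for (i in seq_len(n)) {
    r0 <- runif(1, radiusRange[1], radiusRange[2])
    nl <- sample(rep(lobeCounts, 2), 1)
    side <- ceiling(4 * (r0 + r0 * 0.8)) + 21
    canvas <- matrix(0L, side, side)
    c0 <- c(side / 2, side / 2)
    lobes <- list()
    centers <- matrix(c0, 1, 2)
    radii <- r0
    if (nl > 1) {
      ang <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = nl + 1)[1:nl]
      for (a in ang) {
        r1 <- r0 * runif(1, 0.45, 0.6)
        d <- r0 + r1 * runif(1, 0.0, 0.3)  # overlapping lobe
        lobes[[length(lobes) + 1L]] <- list(r = r1, d = d)
        centers <- rbind(centers, c0 + d * c(cos(a), sin(a)))
        radii <- c(radii, r1)
      }
    }
    canvas <- .rasterDiscs(canvas, centers, radii, 1L)
    geo <- .discUnionGeometry(r0, lobes)
    masks[[i]] <- labelMask(canvas, pixelSize)
    gt[[i]] <- data.frame(mask = i, lobes = nl, area_px = geo$area,
                          perimeter_px = geo$perimeter,
                          true_circularity =
                            4 * pi * geo$area / geo$perimeter^2)
  }
  list(masks = masks, groundTruth = do.call(rbind, gt))
}

#' Generate a photon-count PLA image with known spots
#'
#' Nuclei are rasterized as ellipses whose areas span the 100-400 um^2
#' acceptance gate (some deliberately outside); spots are Gaussian photon
#' peaks placed near retained nuclei over a Poisson background. The
#' background rate is validated at generation: its LoG response must stay
#' well below the detection threshold.
#'
#' @param n_nuclei number of nuclei.
#' @param spotsPerCell integer, spots per gated nucleus (scalar or vector).
#' @param peakPhotons spot peak amplitude in photons.
#' @param background Poisson background rate (photons/pixel).
#' @param spotSigma spot Gaussian width (px).
#' @param pixelSize um per px.
#' @param outOfGate number of nuclei deliberately generated outside the
#'   area gate (small and large).
#' @param seed integer seed.
#' @return list: \code{photons} (integer matrix), \code{nuclei}
#'   (\linkS4class{LabelMask}), \code{groundTruth} (spot coordinates and
#'   intended nucleus, nucleus areas, flags for overlapping spots).
#' @export
genPlaImage <- function(n_nuclei = 10, spotsPerCell = 5, peakPhotons = 12,
                        background = 0.2, spotSigma = 1.2,
                        pixelSize = 0.142, outOfGate = 0, seed = 1L) {
  set.seed(seed)
  # background must be far below threshold after LoG: peak response of a
  # lone background photon is |k(0,0)| ~ 0.3 photons
  stopifnot(background < 2)
  nTot <- n_nuclei + outOfGate
  grid <- ceiling(sqrt(nTot))
  # spacing: largest gated nucleus (400 um^2 at 0.142 um/px ~ 75 px
  # radius, eccentric up to 1.25x) plus the spot placement annulus must
  # stay inside one grid cell
  cellPx <- 2 * (ceiling(sqrt(480 / pi) / pixelSize * 1.25) + 40)
  side <- grid * cellPx
  lab <- matrix(0L, side, side)
  gtN <- list(); gtS <- list()
  # gated nuclear radius: area 100-400 um^2 -> r = sqrt(A/pi)/pixelSize
  rFor <- function(areaUm2) sqrt(areaUm2 / pi) / pixelSize
  areas <- runif(n_nuclei, 150, 350)
  if (outOfGate > 0)
    areas <- c(areas, rep(c(60, 480), length.out = outOfGate))
  photons <- matrix(rpois(side * side, background), side, side)
  spotId <- 0L
  for (i in seq_len(nTot)) {
    gx <- ((i - 1) %% grid) * cellPx + cellPx / 2
    gy <- ((i - 1) %/% grid) * cellPx + cellPx / 2
    r <- rFor(areas[i])
    ecc <- runif(1, 0.8, 1.25)
    xr <- max(1, floor(gx - r * 1.3)):min(side, ceiling(gx + r * 1.3))
    yr <- max(1, floor(gy - r * 1.3)):min(side, ceiling(gy + r * 1.3))
    sub <- outer(xr - gx, yr - gy,
                 function(a, b) (a * ecc)^2 + (b / ecc)^2) <= r^2
    lab[xr, yr][sub] <- i
    gtN[[i]] <- data.frame(nucleus = i,
                           area_um2 = sum(sub) * pixelSize^2,
                           x = gx, y = gy)
    nSpots <- if (length(spotsPerCell) > 1) spotsPerCell[i] else spotsPerCell
    for (s in seq_len(nSpots)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- r * 1.3 + runif(1, 4, 18)
      sx <- round(gx + rad * cos(ang)); sy <- round(gy + rad * sin(ang))
      sx <- min(max(sx, 8), side - 8); sy <- min(max(sy, 8), side - 8)
      spotId <- spotId + 1L
      h <- 6
      xs <- (sx - h):(sx + h); ys <- (sy - h):(sy + h)
      bump <- peakPhotons *
        exp(-outer(xs - sx, ys - sy, function(a, b) a^2 + b^2) /
              (2 * spotSigma^2))
      photons[xs, ys] <- photons[xs, ys] + round(bump)
      gtS[[spotId]] <- data.frame(spot = spotId, x = sx, y = sy,
                                  nucleus = i)
    }
  }
  gtS <- if (length(gtS)) do.call(rbind, gtS) else
    data.frame(spot = integer(0), x = numeric(0), y = numeric(0),
               nucleus = integer(0))
  # flag spot pairs closer than 2 sigma
  flagged <- logical(nrow(gtS))
  if (nrow(gtS) > 1) {
    d <- as.matrix(dist(gtS[, c("x", "y")]))
    diag(d) <- Inf
    flagged <- apply(d, 1, min) < 2 * spotSigma
  }
  gtS$overlapping <- flagged
  list(photons = photons, nuclei = labelMask(lab, pixelSize),
       groundTruth = list(nuclei = do.call(rbind, gtN), spots = gtS))
}

#' Generate paired-channel images of cells with known N/C ratios
#'
#' Cells are concentric discs (nucleus inside cell); both channels carry
#' the cell's true N/C ratio as uniform intensities plus Gaussian noise.
#'
#' @param n_cells number of cells.
#' @param trueRatios per-cell true N/C ratios (recycled), or a function
#'   (n) -> ratios.
#' @param noise multiplicative noise sd.
#' @param pixelSize um per px.
#' @param seed integer seed.
#' @return list: \code{channel1}, \code{channel2}, \code{nuclearMask},
#'   \code{cellMask}, \code{groundTruth} (cell, true_nc).
#' @export
genNcCells <- function(n_cells = 20, trueRatios = 2, noise = 0.02,
                       pixelSize = 0.142, seed = 1L) {
  set.seed(seed)
  ratios <- if (is.function(trueRatios)) trueRatios(n_cells) else
    rep_len(trueRatios, n_cells)
  if (any(ratios <= 0)) stop("true ratios must be > 0")
  grid <- ceiling(sqrt(n_cells))
  cellPx <- 96
  side <- grid * cellPx
  nuc <- matrix(0L, side, side); cell <- matrix(0L, side, side)
  ch1 <- matrix(0, side, side); ch2 <- matrix(0, side, side)
  rCell <- 16; rNuc <- 8
  for (i in seq_len(n_cells)) {
    gx <- ((i - 1) %% grid) * cellPx + cellPx / 2
    gy <- ((i - 1) %/% grid) * cellPx + cellPx / 2
    xr <- (gx - rCell - 2):(gx + rCell + 2)
    yr <- (gy - rCell - 2):(gy + rCell + 2)
    d2 <- outer(xr - gx, yr - gy, function(a, b) a^2 + b^2)
    cell[xr, yr][d2 <= rCell^2] <- i
    nuc[xr, yr][d2 <= rNuc^2] <- i
    cytV <- 100
    nucV <- cytV * ratios[i]
    inten <- ifelse(d2 <= rNuc^2, nucV, ifelse(d2 <= rCell^2, cytV, 0))
    ch1[xr, yr] <- ch1[xr, yr] + inten * (1 + rnorm(length(inten), 0, noise))
    ch2[xr, yr] <- ch2[xr, yr] + inten * (1 + rnorm(length(inten), 0, noise))
  }
  list(channel1 = ch1, channel2 = ch2,
       nuclearMask = labelMask(nuc, pixelSize),
       cellMask = labelMask(cell, pixelSize),
       groundTruth = data.frame(cell = seq_len(n_cells), true_nc = ratios))
}

#' Generate per-outgrowth transcript profiles for model scaling
#'
#' Relative transcript levels for the mapped transport genes, lognormal
#' around 1 with the given dispersion (log sd). A subset of genes can be
#' given their own dispersion to emulate gene-specific heterogeneity.
#'
#' @param n_outgrowths number of profiles.
#' @param dispersion log-scale sd of relative levels (scalar or named per
#'   gene).
#' @param seed integer seed.
#' @return matrix (outgrowths x genes) of relative levels; attribute
#'   \code{"dispersion"} records the generating values.
#' @export
genModelProfiles <- function(n_outgrowths = 20, dispersion = 0.3,
                             seed = 1L) {
  stopifnot(all(dispersion >= 0))
  set.seed(seed)
  genes <- names(.GENE_MAP)
  disp <- if (length(dispersion) == 1) setNames(rep(dispersion,
    length(genes)), genes) else {
    d <- setNames(rep(0, length(genes)), genes)
    d[names(dispersion)] <- dispersion
    d
  }
  prof <- vapply(genes, function(g)
    rlnorm(n_outgrowths, meanlog = -disp[[g]]^2 / 2, sdlog = disp[[g]]),
    numeric(n_outgrowths))
  rownames(prof) <- sprintf("outgrowth%02d", seq_len(n_outgrowths))
  attr(prof, "dispersion") <- disp
  prof
}
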