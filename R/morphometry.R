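## Image quantification operators: outgrowth circularity with
## size-percentile stratification, Laplacian-of-Gaussian spot calling for
## proximity ligation assays, and colocalized nuclear/cytoplasmic
## intensity ratios.

## perimeter of one labelled object: Moore boundary contour (EBImage
## ocontour), smoothed by a circular moving average (window w) to suppress
## the digital staircase, then the closed-polygon length. Window 3 keeps
## rasterized discs within ~2% of the analytic perimeter while cutting
## square corners by < 1.5%.
.smoothPerimeter <- function(mask01, w = 3L) {
  oc <- EBImage::ocontour(mask01)[[1]]
  n <- nrow(oc)
  if (n < 4) return(4)  # single-pixel scale objects
  k <- rep(1 / w, w)
  sm <- apply(oc, 2, function(v) {
    vv <- c(tail(v, w), v, head(v, w))
    as.numeric(stats::filter(vv, k))[(w + 1):(w + n)]
  })
  d <- diff(rbind(sm, sm[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Per-object circularity of a labelled mask
#'
#' Circularity is 4 pi area / perimeter^2 (1 for a disc). The perimeter is
#' estimated from the smoothed boundary contour (documented digital
#' tolerance delta = 0.05, so circularity <= 1.05). Objects touching the
#' image border are flagged.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @return data.frame: label, area_px, area_um2, perimeter_um, circularity,
#'   on_border.
#' @examples
#' m <- genOutgrowthMasks(1, seed = 1)
#' circularity(m$masks[[1]])
#' @export
circularity <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  lab <- mask@labels
  px <- mask@pixelSize
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (!length(ids)) stop("mask contains no labelled objects")
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  rows <- lapply(ids, function(id) {
    obj <- (lab == id) * 1
    a <- sum(obj)
    p <- .smoothPerimeter(obj)
    data.frame(label = id, area_px = a, area_um2 = a * px^2,
               perimeter_um = p * px,
               circularity = 4 * pi * a / p^2,
               on_border = id %in% border)
  })
  do.call(rbind, rows)
}

#' Retain the largest objects by area percentile
#'
#' Keeps records whose area is at or above the (100 - upper_percent)th
#' area percentile (type-7 quantile); ties at the threshold are kept.
#'
#' @param records data.frame from [circularity()] (needs an area column,
#'   \code{area_px} or \code{area_um2}).
#' @param upper_percent upper percentile band to keep (default 35, i.e.
#'   the upper 35th percentile of outgrowths by size).
#' @return the retained subset.
#' @export
stratifyBySize <- function(records, upper_percent = 35) {
  if (nrow(records) < 3) stop("need at least 3 records")
  area <- if ("area_px" %in% names(records)) records$area_px else
    records$area_um2
  if (upper_percent >= 100) return(records)
  thr <- quantile(area, 1 - upper_percent / 100, type = 7, names = FALSE)
  records[area >= thr, , drop = FALSE]
}

#' Compare circularity between groups
#'
#' Two-sided Wilcoxon rank-sum test with median and interquartile-range
#' summaries (the notched-boxplot view of the same comparison).
#'
#' @param groupA,groupB numeric circularity vectors (>= 3 each).
#' @return list: p.value, medians, iqrs (2x2), n.
#' @export
compareCircularity <- function(groupA, groupB) {
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("need at least 3 values per group")
  wt <- wilcox.test(groupA, groupB, alternative = "two.sided",
                    exact = length(groupA) < 50 && length(groupB) < 50 &&
                      !anyDuplicated(c(groupA, groupB)))
  list(p.value = unname(wt$p.value),
       medians = c(A = median(groupA), B = median(groupB)),
       iqrs = rbind(A = quantile(groupA, c(0.25, 0.75), names = FALSE),
                    B = quantile(groupB, c(0.25, 0.75), names = FALSE)),
       n = c(A = length(groupA), B = length(groupB)))
}

## rotationally symmetric Laplacian-of-Gaussian kernel, zero-mean
.logKernel <- function(size = 15L, sigma = 1) {
  h <- (size - 1) / 2
  g <- outer(-h:h, -h:h, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g <- g / sum(g)
  xy2 <- outer(-h:h, -h:h, function(x, y) x^2 + y^2)
  k <- g * (xy2 - 2 * sigma^2) / sigma^4
  k - mean(k)
}

#' Call proximity-ligation spots and assign them to nuclei
#'
#' The photon-count image is filtered with a rotationally symmetric
#' Laplacian-of-Gaussian kernel (default 15 x 15, sigma 1 px); the negated
#' response, expressed in photons, is thresholded (default 5 photons per
#' pixel). Connected components above threshold become spots (one spot per
#' component, located at the component's response maximum). Nuclei are
#' gated to the given area range; each spot is assigned to the nearest
#' retained nucleus by centroid distance (no maximum distance unless
#' \code{maxDistance} is set).
#'
#' @param photons integer matrix of photon counts.
#' @param nuclei a \linkS4class{LabelMask} of nuclear objects aligned with
#'   the image.
#' @param logSize,logSigma LoG kernel size (px) and standard deviation (px).
#' @param threshold photons-per-pixel threshold on the negated response.
#' @param nucleusArea admissible nuclear area range in um^2 (default
#'   100-400).
#' @param maxDistance optional maximum spot-to-nucleus centroid distance
#'   (px); spots farther away are left unassigned.
#' @return list: \code{spots} (data.frame x, y, peak, nucleus),
#'   \code{countsPerNucleus} (named integer), \code{retainedNuclei}.
#' @export
plaSpots <- function(photons, nuclei, logSize = 15L, logSigma = 1,
                     threshold = 5, nucleusArea = c(100, 400),
                     maxDistance = NULL) {
  stopifnot(is.matrix(photons), is(nuclei, "LabelMask"),
            all(dim(photons) == dim(nuclei@labels)))
  if (any(photons < 0)) stop("photon image must be non-negative")
  px <- nuclei@pixelSize
  lab <- nuclei@labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  areas <- vapply(ids, function(i) sum(lab == i) * px^2, 0)
  retained <- ids[areas >= nucleusArea[1] & areas <= nucleusArea[2]]
  centroid <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    colMeans(idx)
  }
  nucCent <- t(vapply(ids, function(i) centroid(lab == i), numeric(2)))
  resp <- -EBImage::filter2(EBImage::Image(photons),
                            .logKernel(logSize, logSigma))
  resp <- EBImage::imageData(resp)
  above <- resp > threshold
  if (!any(above) || length(retained) == 0) {
    if (length(retained) == 0)
      warning("no nuclei retained by the area gate")
    return(list(
      spots = data.frame(x = numeric(0), y = numeric(0),
                         peak = numeric(0), nucleus = integer(0),
                         retained = logical(0)),
      countsPerNucleus = setNames(integer(length(retained)),
                                  as.character(retained)),
      retainedNuclei = retained))
  }
  comp <- EBImage::bwlabel(EBImage::Image(above * 1))
  comp <- EBImage::imageData(comp)
  spotIds <- seq_len(max(comp))
  spots <- do.call(rbind, lapply(spotIds, function(sid) {
    idx <- which(comp == sid, arr.ind = TRUE)
    pk <- which.max(resp[idx])
    data.frame(x = idx[pk, 1], y = idx[pk, 2],
               peak = max(resp[idx]))
  }))
  # assign each spot to its nearest nucleus among all nuclei; spots whose
  # nucleus fails the area gate are excluded along with the nucleus
  d2 <- outer(spots$x, nucCent[, 1], "-")^2 +
        outer(spots$y, nucCent[, 2], "-")^2
  nearest <- apply(d2, 1, which.min)
  dist <- sqrt(d2[cbind(seq_len(nrow(spots)), nearest)])
  spots$nucleus <- ids[nearest]
  spots$retained <- spots$nucleus %in% retained
  if (!is.null(maxDistance)) {
    spots$retained[dist > maxDistance] <- FALSE
    spots$nucleus[dist > maxDistance] <- NA
  }
  counts <- table(factor(spots$nucleus[spots$retained], levels = retained))
  list(spots = spots,
       countsPerNucleus = setNames(as.integer(counts),
                                   as.character(retained)),
       retainedNuclei = retained)
}

## two-sample quantile normalization: both channels mapped to the average
## sorted profile
.quantileNormalize2 <- function(a, b) {
  ra <- rank(a, ties.method = "first")
  rb <- rank(b, ties.method = "first")
  target <- (sort(a) + sort(b)) / 2
  list(a = matrix(target[ra], nrow(a)), b = matrix(target[rb], nrow(b)))
}

#' Colocalized nuclear/cytoplasmic intensity ratio
#'
#' Each channel is background-corrected with a morphological top-hat
#' (opening subtracted; disc structuring element), the two channels are
#' quantile-normalized to their average sorted profile, and combined by
#' pixel-wise geometric mean into a colocalization-weighted image. Per
#' cell, the ratio of mean colocalized intensity inside the nuclear mask
#' to the mean over the cytoplasm (cell minus nucleus) is returned. Cells
#' with an empty cytoplasmic region are excluded with a note.
#'
#' @param channel1,channel2 intensity matrices.
#' @param nuclearMask,cellMask \linkS4class{LabelMask}s; nucleus labels
#'   must match their cell's label.
#' @param tophatRadius structuring-element radius in px (default 25;
#'   larger than the objects to be preserved).
#' @return data.frame: cell, nc_ratio, nuclear_mean, cytoplasm_mean.
#' @export
ncIntensity <- function(channel1, channel2, nuclearMask, cellMask,
                        tophatRadius = 25) {
  stopifnot(all(dim(channel1) == dim(channel2)),
            all(dim(channel1) == dim(nuclearMask@labels)),
            all(dim(channel1) == dim(cellMask@labels)))
  brush <- EBImage::makeBrush(2 * tophatRadius + 1, shape = "disc")
  tophat <- function(m) {
    im <- EBImage::Image(m / max(m, 1))
    EBImage::imageData(im - EBImage::opening(im, brush)) * max(m, 1)
  }
  c1 <- tophat(channel1); c2 <- tophat(channel2)
  qn <- .quantileNormalize2(c1, c2)
  coloc <- sqrt(pmax(qn$a, 0) * pmax(qn$b, 0))
  nuc <- nuclearMask@labels; cell <- cellMask@labels
  ids <- sort(setdiff(unique(as.vector(cell)), 0L))
  rows <- list()
  for (id in ids) {
    inNuc <- nuc == id
    inCyt <- cell == id & !inNuc
    if (!any(inCyt)) {
      message("cell ", id, " has no cytoplasmic pixels; excluded")
      next
    }
    if (!any(inNuc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      cell = id,
      nc_ratio = mean(coloc[inNuc]) / mean(coloc[inCyt]),
      nuclear_mean = mean(coloc[inNuc]),
      cytoplasm_mean = mean(coloc[inCyt]))
  }
  do.call(rbind, rows)
}
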