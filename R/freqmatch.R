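## Stochastic frequency matching: flag heterogeneously expressed genes
## against pool-and-split technical references, count per-gene expression
## events in treated outgrowths against control percentiles, and classify
## genes whose event frequency matches the phenotype penetrance under an
## inverse-binomial band.

#' Heterogeneity screen for single-outgrowth transcriptomes
#'
#' A variance-ratio surrogate for stochastic-profiling heterogeneity
#' filtering. Genes failing detection in more than half of the samples of
#' the tested condition are excluded. Pool-and-split samples whose
#' log2 fold-range exceeds \code{max_fc_reproducible} are excluded as
#' irreproducible. For each retained gene a one-sided variance-ratio test
#' compares the biological-sample variance against the larger of the
#' pool-and-split variance and a coefficient-of-variation floor
#' (\code{(log2(1 + ref_cv))^2} on the log2 scale); p-values are
#' Benjamini-Hochberg adjusted and flagged at \code{q < fdr_het}.
#' Pool-and-split variances significantly above the floor (chi-square test
#' at BH \code{fdr_sampling}) use the measured technical variance as the
#' reference; otherwise the floor applies.
#'
#' @param se \code{SummarizedExperiment} with a log2 expression assay
#'   (first assay), optional logical assay \code{"detected"}, and colData
#'   columns \code{condition} and \code{sample_type}
#'   ("biological"/"poolsplit").
#' @param condition which condition to screen (default "plusAP").
#' @param params list of screen parameters: \code{detection_p} (detection
#'   call threshold used by the upstream platform; recorded only),
#'   \code{max_fc_reproducible}, \code{fdr_sampling}, \code{ref_cv},
#'   \code{fdr_het}.
#' @return a data.frame: gene, varBio, varRef, statistic (variance ratio),
#'   p, q, flagged, excluded (with reason).
#' @export
heterogeneityScreen <- function(se, condition = "plusAP",
                                params = list(detection_p = 0.1,
                                              max_fc_reproducible = 5,
                                              fdr_sampling = 0.05,
                                              ref_cv = 0.2,
                                              fdr_het = 0.1)) {
  cd <- SummarizedExperiment::colData(se)
  stopifnot(all(c("condition", "sample_type") %in% colnames(cd)))
  bio <- which(cd$condition == condition & cd$sample_type == "biological")
  ps <- which(cd$condition == condition & cd$sample_type == "poolsplit")
  if (length(ps) < 3) stop("technical reference required: fewer than 3 ",
                           "pool-and-split samples in condition ", condition)
  if (length(bio) < 3) stop("fewer than 3 biological samples in condition ",
                            condition)
  x <- SummarizedExperiment::assay(se, 1)
  det <- if ("detected" %in% SummarizedExperiment::assayNames(se))
    SummarizedExperiment::assay(se, "detected") else
    matrix(TRUE, nrow(x), ncol(x))
  genes <- rownames(x)
  nBio <- length(bio); nPs <- length(ps)
  varBio <- apply(x[, bio, drop = FALSE], 1, var)
  varPs <- apply(x[, ps, drop = FALSE], 1, var)
  fcPs <- apply(x[, ps, drop = FALSE], 1, function(v) diff(range(v)))
  detFrac <- rowMeans(det[, c(bio, ps), drop = FALSE])

  excluded <- rep(NA_character_, length(genes))
  excluded[detFrac < 0.5] <- "undetected"
  excluded[is.na(excluded) & fcPs > log2(params$max_fc_reproducible)] <-
    "irreproducible"

  floorVar <- (log2(1 + params$ref_cv))^2
  # pool-split variance significantly above the CV floor?
  pSamp <- pchisq((nPs - 1) * varPs / floorVar, df = nPs - 1,
                  lower.tail = FALSE)
  useMeasured <- p.adjust(pSamp, "BH") < params$fdr_sampling
  varRef <- ifelse(useMeasured, varPs, floorVar)
  varRef <- pmax(varRef, floorVar)

  stat <- varBio / varRef
  p <- pf(stat, df1 = nBio - 1, df2 = nPs - 1, lower.tail = FALSE)
  p[!is.na(excluded)] <- NA
  q <- rep(NA_real_, length(p))
  keep <- is.na(excluded)
  q[keep] <- p.adjust(p[keep], "BH")
  data.frame(gene = genes, varBio = varBio, varRef = varRef,
             statistic = stat, p = p, q = q,
             flagged = !is.na(q) & q < params$fdr_het,
             excluded = excluded, row.names = NULL)
}

#' Control percentile thresholds for one gene
#'
#' Empirical 10th and 90th percentiles of the untreated (minus-AP) control
#' values, computed by linear interpolation between closest order
#' statistics (type-7 quantiles).
#'
#' @param x numeric vector of control values (>= 5 finite values).
#' @param probs the two percentiles (default c(0.1, 0.9)).
#' @return named numeric c(p10, p90).
#' @examples
#' controlThresholds(1:20)  # c(p10 = 2.9, p90 = 18.1)
#' @export
controlThresholds <- function(x, probs = c(0.1, 0.9)) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need at least 5 finite control values")
  q <- quantile(x, probs, type = 7, names = FALSE)
  c(p10 = q[1], p90 = q[2])
}

#' Count single-outgrowth expression events against control thresholds
#'
#' Events are counted with strict inequalities: values exactly at a
#' threshold are not events (conservative tie handling).
#'
#' @param x numeric vector of treated-condition values.
#' @param thresholds c(p10, p90) from [controlThresholds()].
#' @return named integer c(n_above, n_below).
#' @export
countEvents <- function(x, thresholds) {
  x <- x[is.finite(x)]
  c(n_above = sum(x > thresholds[["p90"]]),
    n_below = sum(x < thresholds[["p10"]]))
}

#' Inverse-binomial frequency band
#'
#' Builds the expected-event band implied by a binomial phenotype
#' penetrance: endpoints are the smallest integers k with CDF(k) >= level,
#' with the CDF obtained by exact summation of the probability mass
#' function (no normal approximation).
#'
#' @param n number of trials (profiled outgrowths).
#' @param p success probability (phenotype penetrance).
#' @param iqr_levels,ci_levels quantile levels of the interquartile and 90%
#'   bands.
#' @return a \linkS4class{BinomialBand}.
#' @examples
#' binomialBand(20, 0.35)  # expected 7, IQR [6, 8], 90% CI [4, 11]
#' @export
binomialBand <- function(n, p, iqr_levels = c(0.25, 0.75),
                         ci_levels = c(0.05, 0.95)) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  n <- as.integer(n)
  cdf <- cumsum(dbinom(0:n, n, p))
  invert <- function(level) {
    k <- which(cdf >= level - 1e-12)[1] - 1L
    as.integer(k)
  }
  new("BinomialBand", n = n, p = p, expected = n * p,
      iqr = vapply(iqr_levels, invert, 1L),
      ci90 = vapply(ci_levels, invert, 1L))
}

#' @describeIn binomialBand expected event count n*p.
#' @param band a BinomialBand.
#' @export
bandExpected <- function(band) band@expected

#' @describeIn binomialBand interquartile band endpoints.
#' @export
bandIqr <- function(band) band@iqr

#' @describeIn binomialBand 90% band endpoints.
#' @export
bandCi90 <- function(band) band@ci90

setMethod("show", "BinomialBand", function(object) {
  cat(sprintf(
    "BinomialBand B(%d, %.3g): expected %.3g, IQR [%d, %d], 90%% CI [%d, %d]\n",
    object@n, object@p, object@expected, object@iqr[1], object@iqr[2],
    object@ci90[1], object@ci90[2]))
})

#' Classify per-gene event counts against a frequency band
#'
#' Genes whose matched event count falls inside the interquartile band are
#' high-priority; inside the 90% band, candidates; otherwise unmatched.
#'
#' @param calls data.frame with columns \code{n_above}, \code{n_below}
#'   (from [countEvents()]) and optionally \code{gene}.
#' @param band \linkS4class{BinomialBand} whose \code{n} equals the number
#'   of treated biological samples the counts were taken over.
#' @param nSamples the treated biological sample count (checked against
#'   \code{band@n}).
#' @param mode how up and down events combine into the matched count:
#'   "max" (default; avoids double-counting bidirectional genes) or "sum".
#' @return \code{calls} with added columns \code{direction} ("up"/"down";
#'   argmax of the two counts, ties resolved "up" and flagged in
#'   \code{tie}), \code{matched_count} and \code{tier}.
#' @export
classifyCalls <- function(calls, band, nSamples = band@n,
                          mode = c("max", "sum")) {
  mode <- match.arg(mode)
  if (nSamples != band@n)
    stop("band trials (", band@n, ") do not match sample count (",
         nSamples, ")")
  up <- calls$n_above; dn <- calls$n_below
  calls$direction <- ifelse(dn > up, "down", "up")
  calls$tie <- up == dn & up > 0
  calls$matched_count <- if (mode == "max") pmax(up, dn) else up + dn
  mc <- calls$matched_count
  calls$tier <- ifelse(
    mc >= band@iqr[1] & mc <= band@iqr[2], "high_priority",
    ifelse(mc >= band@ci90[1] & mc <= band@ci90[2], "candidate",
           "unmatched"))
  calls
}

#' Stochastic frequency matching, end to end
#'
#' For each gene (optionally restricted to heterogeneity-flagged genes),
#' derives the control thresholds from minus-AP biological samples, counts
#' plus-AP biological events, and classifies the matched count against the
#' binomial band implied by the phenotype penetrance.
#'
#' @param se \code{SummarizedExperiment} as in [heterogeneityScreen()].
#' @param p phenotype penetrance (default 0.35).
#' @param genes optional character vector restricting the genes scored.
#' @param mode matched-count combination, see [classifyCalls()].
#' @param controlCondition,treatedCondition condition labels.
#' @return data.frame of per-gene thresholds, counts, direction, tier.
#' @export
frequencyMatch <- function(se, p = 0.35, genes = NULL,
                           mode = c("max", "sum"),
                           controlCondition = "minusAP",
                           treatedCondition = "plusAP") {
  mode <- match.arg(mode)
  cd <- SummarizedExperiment::colData(se)
  x <- SummarizedExperiment::assay(se, 1)
  ctl <- which(cd$condition == controlCondition &
                 cd$sample_type == "biological")
  trt <- which(cd$condition == treatedCondition &
                 cd$sample_type == "biological")
  if (!is.null(genes)) x <- x[intersect(rownames(x), genes), , drop = FALSE]
  band <- binomialBand(length(trt), p)
  rows <- lapply(rownames(x), function(g) {
    thr <- controlThresholds(x[g, ctl])
    ev <- countEvents(x[g, trt], thr)
    data.frame(gene = g, p10 = thr[["p10"]], p90 = thr[["p90"]],
               n_above = ev[["n_above"]], n_below = ev[["n_below"]])
  })
  calls <- do.call(rbind, rows)
  classifyCalls(calls, band, mode = mode)
}

#' Arcsine-transformed penetrance summary
#'
#' Per-replicate phenotype proportions are variance-stabilized as
#' x = arcsin(sqrt(s/t)); the mean, standard error and back-transformed
#' proportion are returned. Replicates with zero total are excluded with a
#' note.
#'
#' @param successes,totals integer vectors per replicate.
#' @return list with \code{transformed} values, \code{mean}, \code{se},
#'   \code{proportion} (back-transformed mean), \code{excluded} count.
#' @examples
#' penetranceStats(c(35, 30, 40), c(100, 100, 100))
#' @export
penetranceStats <- function(successes, totals) {
  stopifnot(length(successes) == length(totals),
            all(totals >= successes), all(successes >= 0))
  bad <- totals == 0
  if (any(bad)) message(sum(bad), " replicate(s) with zero total excluded")
  s <- successes[!bad]; t <- totals[!bad]
  z <- asin(sqrt(s / t))
  m <- mean(z)
  list(transformed = z, mean = m,
       se = if (length(z) > 1) sd(z) / sqrt(length(z)) else NA_real_,
       proportion = sin(m)^2, excluded = sum(bad))
}

#' Two-sided t test of penetrance between groups after arcsine transform
#'
#' @param successes1,totals1,successes2,totals2 per-replicate counts for
#'   the two groups.
#' @return the \code{htest} from [stats::t.test()] on transformed values.
#' @export
penetranceTest <- function(successes1, totals1, successes2, totals2) {
  a <- penetranceStats(successes1, totals1)
  b <- penetranceStats(successes2, totals2)
  t.test(a$transformed, b$transformed, alternative = "two.sided")
}
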