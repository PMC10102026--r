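test_that("binomial band endpoints match exact enumeration for many n, p", {
  # stats::qbinom serves as the independent oracle for the hand-summed CDF
  for (n in c(5, 10, 20, 35, 50)) for (p in seq(0.05, 0.95, by = 0.15)) {
    b <- binomialBand(n, p)
    expect_identical(bandIqr(b), as.integer(qbinom(c(0.25, 0.75), n, p)),
                     label = sprintf("iqr n=%d p=%.2f", n, p))
    expect_identical(bandCi90(b), as.integer(qbinom(c(0.05, 0.95), n, p)),
                     label = sprintf("ci n=%d p=%.2f", n, p))
    expect_true(bandCi90(b)[1] <= bandIqr(b)[1])
    expect_true(bandIqr(b)[2] <= bandCi90(b)[2])
  }
})

test_that("the phenotype-penetrance band reproduces the printed intervals", {
  b <- binomialBand(20, 0.35)
  expect_equal(bandExpected(b), 7)
  expect_identical(bandIqr(b), c(6L, 8L))
  expect_identical(bandCi90(b), c(4L, 11L))
  # degenerate probability
  b0 <- binomialBand(12, 0)
  expect_equal(bandExpected(b0), 0)
  expect_identical(bandIqr(b0), c(0L, 0L))
  expect_identical(bandCi90(b0), c(0L, 0L))
  b5 <- binomialBand(10, 0.5)
  expect_identical(bandIqr(b5), c(4L, 6L))
  expect_identical(bandCi90(b5), c(2L, 8L))
})

test_that("control thresholds follow the closest-rank interpolation", {
  expect_equal(controlThresholds(1:20), c(p10 = 2.9, p90 = 18.1))
  expect_equal(controlThresholds(rep(4, 8)), c(p10 = 4, p90 = 4))
  x <- c(rnorm(19), 1e6)
  thr <- controlThresholds(x)
  expect_lte(thr[["p90"]], max(x))
  expect_true(is.finite(thr[["p90"]]))
  expect_error(controlThresholds(c(1, 2, 3)), "at least 5")
})

test_that("event counting uses strict inequalities", {
  thr <- c(p10 = 2.9, p90 = 18.1)
  inside <- seq(3, 18, length.out = 20)
  expect_equal(countEvents(inside, thr), c(n_above = 0L, n_below = 0L))
  x <- c(rep(19, 7), seq(5, 15, length.out = 13))
  expect_equal(countEvents(x, thr), c(n_above = 7L, n_below = 0L))
  # a value exactly at the threshold is not an event
  expect_equal(countEvents(c(18.1, 2.9, 10), thr),
               c(n_above = 0L, n_below = 0L))
  expect_equal(countEvents(numeric(0), thr),
               c(n_above = 0L, n_below = 0L))
})

test_that("classification tiers follow the band semantics", {
  band <- binomialBand(20, 0.35)
  calls <- data.frame(gene = letters[1:4],
                      n_above = c(7L, 11L, 12L, 3L),
                      n_below = c(0L, 0L, 0L, 0L))
  out <- classifyCalls(calls, band)
  expect_equal(out$tier,
               c("high_priority", "candidate", "unmatched", "unmatched"))
  expect_equal(out$matched_count, c(7L, 11L, 12L, 3L))
  # direction is the argmax; ties resolve up and are flagged
  calls2 <- data.frame(n_above = c(2L, 5L, 4L), n_below = c(6L, 5L, 1L))
  out2 <- classifyCalls(calls2, band)
  expect_equal(out2$direction, c("down", "up", "up"))
  expect_equal(out2$tie, c(FALSE, TRUE, FALSE))
  # sum mode combines both tails
  out3 <- classifyCalls(calls2, band, mode = "sum")
  expect_equal(out3$matched_count, c(8L, 10L, 5L))
  expect_error(classifyCalls(calls, band, nSamples = 16), "do not match")
})

test_that("classification is invariant to joint monotone transforms", {
  set.seed(3)
  ctl <- rnorm(20); trt <- rnorm(20, 0.5)
  thr <- controlThresholds(ctl)
  ev <- countEvents(trt, thr)
  f <- function(x) exp(x / 2)  # strictly increasing
  ev2 <- countEvents(f(trt), c(p10 = f(thr[["p10"]]),
                               p90 = f(thr[["p90"]])))
  expect_identical(ev, ev2)
})

test_that("heterogeneity screen is calibrated on null data", {
  set.seed(5)
  se <- genExpressionCohort(cohortSpec(n_genes = 1000,
                                       frac_heterogeneous = 0,
                                       n_matched = 0, seed = 51))
  het <- heterogeneityScreen(se)
  expect_lte(sum(het$flagged), 0.1 * 1000)
})

test_that("heterogeneity screen recovers planted high-variance genes", {
  # 50 planted genes with 10x the biological log-variance among 1000
  set.seed(6)
  nG <- 1000; nB <- 20; nP <- 16
  sdNull <- 0.25
  x <- matrix(rnorm(nG * 2 * (nB + nP), 8, sdNull), nG)
  planted <- 1:50
  bioCols <- 1:nB  # plusAP biological block
  x[planted, bioCols] <- rnorm(50 * nB, 8, sdNull * sqrt(10))
  samples <- data.frame(
    condition = rep(c("plusAP", "minusAP"), each = nB + nP),
    sample_type = rep(rep(c("biological", "poolsplit"), c(nB, nP)), 2))
  rownames(x) <- sprintf("g%04d", seq_len(nG))
  colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = x),
    colData = S4Vectors::DataFrame(samples))
  het <- heterogeneityScreen(se)
  expect_gte(mean(het$flagged[planted]), 0.9)
})

test_that("genes undetected in most samples are excluded", {
  se <- genExpressionCohort(cohortSpec(n_genes = 50, n_matched = 0,
                                       frac_heterogeneous = 0, seed = 9))
  plusAP <- SummarizedExperiment::colData(se)$condition == "plusAP"
  det <- SummarizedExperiment::assay(se, "detected")
  det[1, which(plusAP)[1:30]] <- FALSE  # undetected in most plusAP samples
  SummarizedExperiment::assay(se, "detected") <- det
  het <- heterogeneityScreen(se)
  expect_equal(het$excluded[1], "undetected")
  expect_true(is.na(het$q[1]))
})

test_that("pool-and-split reference is required", {
  se <- genExpressionCohort(cohortSpec(n_genes = 20, n_matched = 0,
                                       frac_heterogeneous = 0, seed = 10))
  keep <- SummarizedExperiment::colData(se)$sample_type == "biological"
  expect_error(heterogeneityScreen(se[, keep]), "technical reference")
})

test_that("penetrance statistics use the arcsine square-root transform", {
  expect_equal(penetranceStats(c(0, 0, 0), c(10, 10, 10))$mean, 0)
  expect_equal(penetranceStats(c(10, 10), c(10, 10))$mean, pi / 2)
  st <- penetranceStats(c(35, 30, 40), c(100, 100, 100))
  expect_equal(st$proportion, sin(mean(asin(sqrt(c(.35, .3, .4)))))^2)
  expect_message(penetranceStats(c(1, 0), c(10, 0)), "zero total")
})

test_that("the penetrance t test holds its type-I error at equal p", {
  set.seed(12)
  sims <- replicate(600, {
    s1 <- rbinom(8, 200, 0.35); s2 <- rbinom(8, 200, 0.35)
    penetranceTest(s1, rep(200, 8), s2, rep(200, 8))$p.value
  })
  expect_gt(mean(sims < 0.05), 0.02)
  expect_lt(mean(sims < 0.05), 0.09)
})
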