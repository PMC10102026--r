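test_that("all generators are pure functions of spec and seed", {
  a <- genExpressionCohort(cohortSpec(n_genes = 100, seed = 5))
  b <- genExpressionCohort(cohortSpec(n_genes = 100, seed = 5))
  expect_identical(SummarizedExperiment::assay(a, 1),
                   SummarizedExperiment::assay(b, 1))
  m1 <- genOutgrowthMasks(3, seed = 6); m2 <- genOutgrowthMasks(3, seed = 6)
  expect_identical(m1$masks[[2]]@labels, m2$masks[[2]]@labels)
  p1 <- genPlaImage(n_nuclei = 3, seed = 7)
  p2 <- genPlaImage(n_nuclei = 3, seed = 7)
  expect_identical(p1$photons, p2$photons)
  n1 <- genNcCells(4, seed = 8); n2 <- genNcCells(4, seed = 8)
  expect_identical(n1$channel1, n2$channel1)
  pr1 <- genModelProfiles(5, seed = 9); pr2 <- genModelProfiles(5, seed = 9)
  expect_identical(pr1, pr2)
})

test_that("ground truth is serialized alongside every dataset", {
  se <- genExpressionCohort(cohortSpec(n_genes = 50, seed = 1))
  gt <- S4Vectors::metadata(se)$groundTruth
  expect_named(gt, c("labels", "highState", "spec"))
  expect_equal(length(gt$labels), 50)
  gm <- genOutgrowthMasks(2, seed = 1)
  expect_true(all(c("true_circularity", "lobes") %in%
                    names(gm$groundTruth)))
  pla <- genPlaImage(n_nuclei = 2, seed = 1)
  expect_named(pla$groundTruth, c("nuclei", "spots"))
})

test_that("an impossible cohort specification is rejected", {
  expect_error(cohortSpec(n_genes = 100, frac_heterogeneous = 0.9,
                          n_matched = 30), "impossible")
})

test_that("frequency-matched genes carry the binomial event frequency", {
  counts <- unlist(lapply(1:4, function(s) {
    se <- genExpressionCohort(cohortSpec(seed = s))
    truth <- S4Vectors::metadata(se)$groundTruth$labels
    calls <- frequencyMatch(se,
                            genes = names(truth)[truth == "frequency_matched"])
    calls$matched_count
  }))
  expect_lt(abs(mean(counts) - 7), 1)
})

test_that("single-lobe masks are discs with true circularity 1", {
  gm <- genOutgrowthMasks(4, lobeCounts = 1, seed = 11)
  expect_equal(gm$groundTruth$true_circularity, rep(1, 4),
               tolerance = 1e-9)
  rec <- circularity(gm$masks[[1]])
  expect_lt(abs(rec$circularity - 1), 0.05)
})

test_that("multi-lobe analytic circularity matches the measurement", {
  gm <- genOutgrowthMasks(5, lobeCounts = 3, seed = 12)
  meas <- vapply(gm$masks, function(m) circularity(m)$circularity, 0)
  expect_true(all(abs(meas - gm$groundTruth$true_circularity) < 0.05))
})

test_that("PLA ground truth spans the nuclear area gate when requested", {
  pla <- genPlaImage(n_nuclei = 3, outOfGate = 2, seed = 13)
  a <- pla$groundTruth$nuclei$area_um2
  expect_true(any(a < 100) && any(a > 400))
  expect_true(any(a >= 100 & a <= 400))
})

test_that("nc-cell images realize their target ratios at scale", {
  set.seed(61)
  ratios <- rlnorm(200, 0, 0.4)
  ncc <- genNcCells(200, trueRatios = ratios, noise = 0.05, seed = 61)
  res <- ncIntensity(ncc$channel1, ncc$channel2, ncc$nuclearMask,
                     ncc$cellMask)
  rho <- cor(res$nc_ratio, ncc$groundTruth$true_nc[res$cell],
             method = "spearman")
  expect_gt(rho, 0.95)
  # unit ratio recovered within 2%
  ncc1 <- genNcCells(9, trueRatios = 1, seed = 62)
  res1 <- ncIntensity(ncc1$channel1, ncc1$channel2, ncc1$nuclearMask,
                      ncc1$cellMask)
  expect_lt(abs(median(res1$nc_ratio) - 1), 0.02)
})

test_that("transcript profiles are lognormal around one with the given
           dispersion", {
  prof <- genModelProfiles(500, dispersion = 0.3, seed = 14)
  expect_equal(dim(prof), c(500, 16))
  expect_lt(abs(mean(prof[, "CSE1L"]) - 1), 0.1)
  expect_lt(abs(sd(log(prof[, "CSE1L"])) - 0.3), 0.05)
  # zero dispersion: all profiles identical, hence identical predictions
  prof0 <- genModelProfiles(3, dispersion = 0, seed = 15)
  expect_true(all(prof0 == 1))
})

test_that("CSE1L dispersion alone anticorrelates with predicted N/C", {
  prof <- genModelProfiles(16, dispersion = c(CSE1L = 0.35), seed = 16)
  net <- ksBaseNetwork()
  cargo <- cargoSpec("NLS2x", "classical", 2.5)
  nc <- apply(prof, 1, function(p) {
    ss <- steadyState(addCargo(
      suppressMessages(scaleInitialConditions(p, net)), cargo))
    unname(ncRatio(ss))
  })
  # negative association; rank correlation is diluted only by the flat
  # low-CSE1L shoulder of the dose response
  expect_lt(cor(nc, prof[, "CSE1L"], method = "spearman"), -0.5)
})
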