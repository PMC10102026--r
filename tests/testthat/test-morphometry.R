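rasterDisc <- function(r, pad = 25) {
  n <- 2 * r + 2 * pad + 1
  c0 <- (n + 1) / 2
  m <- matrix(0L, n, n)
  m[outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2) <= r^2] <- 1L
  m
}

test_that("a rasterized disc has circularity near 1", {
  for (r in c(25, 50, 100)) {
    rec <- circularity(labelMask(rasterDisc(r)))
    expect_gt(rec$circularity, 0.95)
    expect_lt(rec$circularity, 1.05)
  }
})

test_that("a filled square has circularity near pi/4", {
  m <- matrix(0L, 201, 201); m[51:150, 51:150] <- 1L
  rec <- circularity(labelMask(m))
  expect_lt(abs(rec$circularity - pi / 4), 0.03)
})

test_that("a multi-lobed blob is less circular than its convex envelope", {
  gm <- genOutgrowthMasks(6, lobeCounts = 3, seed = 21)
  for (i in seq_along(gm$masks)) {
    rec <- circularity(gm$masks[[i]])
    expect_lt(rec$circularity, 0.95)
    # and the measurement tracks the generating geometry
    expect_lt(abs(rec$circularity - gm$groundTruth$true_circularity[i]),
              0.05)
  }
})

test_that("circularity is rotation- and translation-invariant", {
  m <- matrix(0L, 201, 201); m[51:150, 71:170] <- 1L
  base <- circularity(labelMask(m))$circularity
  shifted <- matrix(0L, 201, 201); shifted[31:130, 41:140] <- 1L
  expect_equal(circularity(labelMask(shifted))$circularity, base,
               tolerance = 1e-6)
  rotated <- t(m)  # 90 degree rotation
  expect_equal(circularity(labelMask(rotated))$circularity, base,
               tolerance = 1e-6)
  # approximate scale invariance across disc radii
  cs <- vapply(c(25, 50, 100),
               function(r) circularity(labelMask(rasterDisc(r)))$circularity,
               0)
  expect_lt(diff(range(cs)), 0.05)
})

test_that("objects touching the border are flagged", {
  m <- matrix(0L, 60, 60); m[1:20, 10:30] <- 1L; m[40:55, 40:55] <- 2L
  rec <- circularity(labelMask(m))
  expect_true(rec$on_border[rec$label == 1])
  expect_false(rec$on_border[rec$label == 2])
})

test_that("size stratification keeps the upper area band with ties", {
  rec <- data.frame(label = 1:100, area_px = 1:100,
                    circularity = runif(100))
  expect_equal(nrow(stratifyBySize(rec)), 35)
  # all equal areas: everything retained
  recT <- data.frame(label = 1:10, area_px = rep(7, 10))
  expect_equal(nrow(stratifyBySize(recT)), 10)
  expect_equal(nrow(stratifyBySize(rec, upper_percent = 100)), 100)
  expect_error(stratifyBySize(rec[1:2, ]), "at least 3")
})

test_that("circularity comparison behaves under null and shift", {
  a <- seq(0.3, 0.9, length.out = 20)
  expect_equal(compareCircularity(a, a)$p.value, 1, tolerance = 1e-9)
  set.seed(31)
  g1 <- rnorm(200, 0.5, 0.05); g2 <- rnorm(200, 0.5 + 2 * 0.0675, 0.05)
  expect_lt(compareCircularity(g1, g2)$p.value, 1e-6)
  # permutation null holds its size
  pooled <- rnorm(80, 0.6, 0.1)
  ps <- replicate(400, {
    idx <- sample(80, 40)
    compareCircularity(pooled[idx], pooled[-idx])$p.value
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.11)
})

test_that("a blank photon image yields no spots", {
  nuc <- genPlaImage(n_nuclei = 4, spotsPerCell = 0, background = 0,
                     seed = 41)
  res <- plaSpots(nuc$photons, nuc$nuclei)
  expect_equal(nrow(res$spots), 0)
  expect_true(all(res$countsPerNucleus == 0))
})

test_that("planted spots are recovered and assigned to their nuclei", {
  pla <- genPlaImage(n_nuclei = 6, spotsPerCell = 5, seed = 42)
  res <- plaSpots(pla$photons, pla$nuclei)
  expect_equal(unname(res$countsPerNucleus),
               rep(5L, length(res$retainedNuclei)))
  m <- merge(res$spots, pla$groundTruth$spots, by = c("x", "y"))
  expect_equal(nrow(m), nrow(pla$groundTruth$spots))
  expect_true(all(m$nucleus.x == m$nucleus.y))
})

test_that("nuclei outside the area gate are dropped with their spots", {
  pla <- genPlaImage(n_nuclei = 4, spotsPerCell = 3, outOfGate = 2,
                     seed = 43)
  res <- plaSpots(pla$photons, pla$nuclei)
  gtArea <- pla$groundTruth$nuclei
  gated <- gtArea$nucleus[gtArea$area_um2 >= 100 & gtArea$area_um2 <= 400]
  expect_setequal(res$retainedNuclei, gated)
  # spots generated next to out-of-gate nuclei are excluded
  outSpots <- pla$groundTruth$spots$nucleus %in%
    setdiff(gtArea$nucleus, gated)
  expect_equal(sum(!res$spots$retained), sum(outSpots))
})

test_that("spot counts ignore uniform background below threshold", {
  pla <- genPlaImage(n_nuclei = 4, spotsPerCell = 4, background = 0,
                     seed = 44)
  res1 <- plaSpots(pla$photons, pla$nuclei)
  # a constant offset is annihilated by the zero-mean LoG kernel
  res2 <- plaSpots(pla$photons + 3L, pla$nuclei)
  expect_equal(res1$countsPerNucleus, res2$countsPerNucleus)
})

test_that("nc intensity recovers a constructed two-fold ratio", {
  ncc <- genNcCells(9, trueRatios = 2, seed = 51)
  res <- ncIntensity(ncc$channel1, ncc$channel2, ncc$nuclearMask,
                     ncc$cellMask)
  expect_equal(nrow(res), 9)
  expect_true(all(abs(res$nc_ratio - 2) / 2 < 0.02))
})

test_that("identical channels pass through the geometric mean unchanged
           and swapping channels is symmetric", {
  ncc <- genNcCells(4, trueRatios = c(1, 2, 3, 0.5), seed = 52)
  r12 <- ncIntensity(ncc$channel1, ncc$channel2, ncc$nuclearMask,
                     ncc$cellMask)
  r21 <- ncIntensity(ncc$channel2, ncc$channel1, ncc$nuclearMask,
                     ncc$cellMask)
  expect_equal(r12$nc_ratio, r21$nc_ratio, tolerance = 1e-12)
  # global rescaling of one channel leaves the ratios essentially
  # unchanged (quantile normalization equalizes the two distributions;
  # the shared target profile shifts slightly, hence not bitwise)
  r <- ncIntensity(ncc$channel1 * 7.3, ncc$channel2, ncc$nuclearMask,
                   ncc$cellMask)
  expect_equal(r$nc_ratio, r12$nc_ratio, tolerance = 0.01)
})
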