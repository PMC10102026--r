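test_that("ultrasensitivity index recovers closed-form Hill behaviour", {
  x <- 2^seq(-3, 3, length.out = 50)
  # Hill exponent 4: max log-log slope 4 at the low end
  ui <- ultrasensitivityIndex(list(folds = x, cnRatio = x^4 / (1 + x^4)))
  expect_lt(abs(ui$maxSlope - 4) / 4, 0.05)
  expect_true(ui$monotone)
  # linear curve: slope exactly 1
  ui2 <- ultrasensitivityIndex(list(folds = x, cnRatio = x))
  expect_equal(ui2$maxSlope, 1, tolerance = 1e-8)
  # step-like curve (Hill 50): 10-90% fold range below 1.2
  ui3 <- ultrasensitivityIndex(list(folds = x,
                                    cnRatio = x^50 / (1 + x^50)))
  expect_lt(ui3$transitionWidth, 1.2)
})

test_that("a non-monotone curve is isotonic-fitted and flagged", {
  x <- 2^seq(-2, 2, length.out = 20)
  y <- x + c(rep(0, 10), 0.5, rep(0, 9))  # one bump
  y[11] <- y[10] * 0.8                     # force a decrease
  ui <- ultrasensitivityIndex(list(folds = x, cnRatio = y))
  expect_false(ui$monotone)
  expect_true(is.finite(ui$maxSlope))
})

test_that("disabling the feedback reduces exactly to the base model", {
  net <- ksBaseNetwork()
  cargo <- erbbCargo(320)
  fm0 <- buildFeedbackModel(net, cargo, gainCas = 0, gainImpa = 0)
  res <- feedbackSteadyState(fm0, casFold = 2)
  # reference: plain transport solve with CAS at 2x
  ss <- steadyState(addCargo(scaleSpecies(net, "CAS", 2), cargo))
  expect_equal(res$ncRatio, unname(ncRatio(ss)["ErbB"]), tolerance = 1e-6)
  expect_equal(res$scales, c(1, 1))
  # enabled = FALSE behaves the same as zero gains
  fmOff <- buildFeedbackModel(net, cargo, gainCas = 8, gainImpa = 0.3,
                              enabled = FALSE)
  res2 <- feedbackSteadyState(fmOff, casFold = 2)
  expect_equal(res2$cn, res$cn, tolerance = 1e-6)
})

test_that("feedback constraints are self-consistent at the solution", {
  fm <- buildFeedbackModel(ksBaseNetwork(), erbbCargo(320), 8, 0.3)
  res <- feedbackSteadyState(fm, casFold = 1.5)
  expect_true(res$converged)
  # re-derive the effective scales from the returned distribution
  ss <- steadyState(addCargo(
    scaleSpecies(scaleSpecies(ksBaseNetwork(), "CAS",
                              1.5 * res$scales[1]),
                 "Impa", res$scales[2]),
    erbbCargo(320)))
  vols <- c(cytoplasm = 1200, nucleus = 300, pore = 30)
  amounts <- ss@cargoTotals["ErbB", ] * vols
  fc <- amounts[["cytoplasm"]] / sum(amounts)
  fn <- amounts[["nucleus"]] / sum(amounts)
  expect_equal(res$scales[1], 1 + 8 * fc, tolerance = 1e-4)
  expect_equal(res$scales[2], max(0, 1 - 0.3 * fn), tolerance = 1e-4)
})

test_that("with zero gains the C/N curve is the reciprocal CAS scan", {
  folds <- 2^seq(-1, 2, length.out = 10)
  fm <- buildFeedbackModel(ksBaseNetwork(), erbbCargo(320), 0, 0)
  cv <- cnCurve(fm, folds)
  sc <- sensitivityScan(ksBaseNetwork(), "CAS", folds,
                        list(erbbCargo(320)))
  expect_equal(cv@cnRatio, 1 / sc$nc_ratio, tolerance = 1e-4)
  expect_true(all(cv@converged))
  # C/N non-decreasing in CSE1L over this range
  expect_true(all(diff(cv@cnRatio) > -1e-8))
})

test_that("curve construction validates its grid", {
  fm <- buildFeedbackModel(ksBaseNetwork(), erbbCargo(320), 0, 0)
  expect_error(cnCurve(fm, c(1, 2)), "at least 10")
  expect_error(cnCurve(fm, rev(2^seq(-1, 1, length.out = 11))),
               "strictly increasing")
  expect_error(cnCurve(fm, c(0, 2^seq(-1, 1, length.out = 10))),
               "positive")
})
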