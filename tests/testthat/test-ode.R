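test_that("integration at t = 0 returns the initial state", {
  net <- ksBaseNetwork()
  out <- integrateNetwork(net, t_end = 0)
  sp <- networkSpecies(net)
  expect_equal(unname(unlist(out[1, -1])), sp$init)
})

test_that("conserved moieties are constant along trajectories", {
  net <- addCargo(ksBaseNetwork(), cargoSpec("X", "classical", 32))
  tc <- integrateNetwork(net, t_end = 500, times = c(0, 1, 10, 100, 500))
  m0 <- moietyTotals(net)
  for (i in seq_len(nrow(tc))) {
    mt <- moietyTotals(net, state = unlist(tc[i, -1]))
    expect_lt(max(abs(mt - m0) / pmax(m0, 1e-12)), 1e-6)
  }
  # concentrations stay non-negative within solver tolerance
  expect_true(all(as.matrix(tc[, -1]) > -1e-8))
})

test_that("long-time integration reaches a quiescent state", {
  ss <- ksBaseSteady("nls32")
  expect_true(converged(ss))
  expect_lt(residualNorm(ss), 1e-9)
})

test_that("the Ran gradient points into the nucleus", {
  cc <- ksBaseSteady("nls32")@concentrations
  expect_gt(cc[["RanGTP@nucleus"]], cc[["RanGTP@cytoplasm"]])
  # and it is substantial, as expected from RCC1-in-nucleus /
  # RanGAP-in-cytoplasm topology
  expect_gt(cc[["RanGTP@nucleus"]] / cc[["RanGTP@cytoplasm"]], 100)
})

test_that("steady state agrees with the long-time integration oracle", {
  net <- addCargo(ksBaseNetwork(), cargoSpec("X", "classical", 32))
  ss <- steadyState(net)
  tc <- integrateNetwork(net, t_end = 1e5, times = c(0, 1e5))
  oracle <- unlist(tc[2, -1])
  num <- ss@concentrations
  denom <- pmax(abs(oracle), 1e-6)
  expect_lt(max(abs(num - oracle) / denom), 1e-3)
})

test_that("steady state is independent of the initial guess", {
  net <- addCargo(ksBaseNetwork(), cargoSpec("X", "classical", 32))
  ss1 <- steadyState(net)
  # a second, very different starting point: everything pre-shuffled by a
  # long transient from doubled-then-projected state
  tc <- integrateNetwork(net, t_end = 50, times = c(0, 50))
  ss2 <- steadyState(net, state = unlist(tc[2, -1]))
  expect_true(ss2@converged)
  denom <- pmax(abs(ss1@concentrations), 1e-6)
  expect_lt(max(abs(ss1@concentrations - ss2@concentrations) / denom), 1e-3)
  expect_equal(unname(ncRatio(ss1)), unname(ncRatio(ss2)), tolerance = 1e-3)
})

test_that("higher import affinity gives a higher N/C ratio", {
  expect_gt(ncRatio(ksBaseSteady("nls2.5")), ncRatio(ksBaseSteady("nls32")))
})

test_that("cargo without an import pathway stays cytoplasmic (no leak)", {
  net <- buildNetwork(ksNoLeakConfig())
  ss <- steadyState(addCargo(net, cargoSpec("X", "none")))
  expect_equal(unname(ncRatio(ss)), 0)
})

test_that("without karyopherins cargo stays cytoplasmic (no leak)", {
  cfg <- ksNoLeakConfig()
  ab <- cfg$abundances
  ab$conc[ab$name %in% c("Impa", "Impb", "CAS", "CRM1")] <- 0
  cfg$abundances <- ab
  ss <- steadyState(addCargo(buildNetwork(cfg),
                             cargoSpec("X", "classical", 32)))
  expect_equal(unname(ncRatio(ss)), 0)
  cc <- ss@concentrations
  expect_equal(cc[["X@cytoplasm"]], 1, tolerance = 1e-6)
})

test_that("scaling a species rescales only that species' pools", {
  net <- scaleSpecies(ksBaseNetwork(), "CAS", 2)
  sp <- networkSpecies(net)
  sp0 <- networkSpecies(ksBaseNetwork())
  cas <- sp$name == "CAS"
  expect_equal(sp$init[cas], 2 * sp0$init[cas])
  expect_equal(sp$init[!cas], sp0$init[!cas])
  # Ran scales both nucleotide states
  net2 <- scaleSpecies(ksBaseNetwork(), "Ran", 0.5)
  sp2 <- networkSpecies(net2)
  ranish <- sp2$name %in% c("RanGTP", "RanGDP")
  expect_equal(sp2$init[ranish], 0.5 * sp0$init[ranish])
})
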