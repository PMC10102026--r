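test_that("base network is structurally complete", {
  net <- ksBaseNetwork()
  sp <- networkSpecies(net)
  rx <- networkReactions(net)
  # every base protein participates in at least one reaction
  used <- unique(unlist(c(as.list(rx$reactants), as.list(rx$products))))
  baseProteins <- c("RanGDP", "RanGTP", "NTF2", "RCC1", "RanGAP", "RanBP1",
                    "RanBP3", "Impa", "Impb", "CAS", "CRM1")
  for (p in baseProteins) {
    idx <- which(sp$name == p)
    expect_true(any(idx %in% used), label = paste(p, "participates"))
  }
  expect_setequal(unique(sp$compartment), c("cytoplasm", "nucleus", "pore"))
})

test_that("reaction count matches the hand-enumerated topology", {
  enum <- read.delim(test_path("fixtures", "reaction_enumeration.tsv"))
  expect_equal(reactionCount(ksBaseNetwork()), sum(enum$count))
})

test_that("a configuration with CAS at zero builds with empty CAS pools", {
  cfg <- baseModelConfig()
  cfg$abundances$conc[cfg$abundances$name == "CAS"] <- 0
  net <- buildNetwork(cfg)
  sp <- networkSpecies(net)
  casStates <- vapply(sp$composition, function(co) "CAS" %in% names(co),
                      FALSE)
  expect_true(all(sp$init[casStates] == 0))
})

test_that("invalid configurations are rejected", {
  cfg <- baseModelConfig()
  cfg$abundances$name[1] <- "NotASpecies"
  expect_error(buildNetwork(cfg), "unknown species")
  cfg <- baseModelConfig()
  cfg$abundances$conc[2] <- -1
  expect_error(buildNetwork(cfg), "negative concentration")
  cfg <- baseModelConfig()
  cfg$rates <- cfg$rates[setdiff(names(cfg$rates), "k_rcc1")]
  expect_error(buildNetwork(cfg), "missing rate constant")
  cfg <- baseModelConfig()
  cfg$pores$classes[[1]]$selects <- character(0)
  expect_error(buildNetwork(cfg), "empty selectivity")
})

test_that("adding classical cargo creates the import complex and reactions", {
  net <- addCargo(ksBaseNetwork(), cargoSpec("X", "classical", 32))
  sp <- networkSpecies(net)
  expect_true("X.Impa.Impb" %in% sp$name)
  expect_true("X" %in% sp$name)
  expect_gt(reactionCount(net), reactionCount(ksBaseNetwork()))
  # cargo with NES gains the export complex
  net2 <- addCargo(ksBaseNetwork(),
                   cargoSpec("Y", "classical", 32, hasNes = TRUE,
                             kdExport = 100))
  expect_true("Y.CRM1.RanBP3.RanGTP" %in% networkSpecies(net2)$name)
  # IBB cargo binds importin-beta directly
  net3 <- addCargo(ksBaseNetwork(), cargoSpec("Z", "ibb", 6.5))
  expect_true("Z.Impb" %in% networkSpecies(net3)$name)
  expect_false("Z.Impa.Impb" %in% networkSpecies(net3)$name)
})

test_that("cargo validation errors are raised", {
  net <- addCargo(ksBaseNetwork(), cargoSpec("X", "classical", 32))
  expect_error(addCargo(net, cargoSpec("X", "ibb", 5)), "already in network")
  expect_error(cargoSpec("X", "classical", -2), "kdImport")
  expect_error(cargoSpec("X", "classical", 32, hasNes = TRUE), "kdExport")
})

test_that("two-class pore configuration with a small selective class is
           neutral for admitted cargo", {
  cfg <- baseModelConfig()
  cfg$pores$classes <- list(
    list(count = 3600, selects = "all"),
    list(count = 400, selects = c("impb", "ntf2", "cas")))
  a <- ncRatio(ksBaseSteady("nls32"))
  b <- ncRatio(steadyState(addCargo(buildNetwork(cfg),
                                    cargoSpec("NLS", "classical", 32))))
  expect_lt(abs(b - a) / a, 0.01)
})
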