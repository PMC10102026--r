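# shared fixtures: the base network and a few steady states are expensive,
# so they are built lazily once per test run
.ks_cache <- new.env(parent = emptyenv())

ksBaseNetwork <- function() {
  if (is.null(.ks_cache$net)) .ks_cache$net <- buildNetwork()
  .ks_cache$net
}

ksBaseSteady <- function(cargoKey = "nls32") {
  key <- paste0("ss_", cargoKey)
  if (is.null(.ks_cache[[key]])) {
    cargo <- switch(cargoKey,
      nls32 = cargoSpec("NLS", "classical", 32),
      nls2.5 = cargoSpec("NLS2x", "classical", 2.5),
      ibb = cargoSpec("IBB", "ibb", 6.5))
    .ks_cache[[key]] <- steadyState(addCargo(ksBaseNetwork(), cargo))
  }
  .ks_cache[[key]]
}

# a zero-passive-permeability configuration for the no-import contracts
ksNoLeakConfig <- function() {
  cfg <- baseModelConfig()
  cfg$rates[["k_cargo_passive"]] <- 0
  cfg
}
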