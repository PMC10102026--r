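# Example model-configuration override for readModelConfig().
# Any omitted entry keeps the package default (see baseModelConfig()).
# Abundances are uM of free protein at t = 0; rates are uM^-1 s^-1 for
# bimolecular steps and s^-1 for unimolecular/translocation steps.
abundances:
  - name: CAS
    compartment: cytoplasm
    conc: 3
  - name: RanBP3
    compartment: nucleus
    conc: 0.1
rates:
  k_cargo_passive: 0.1
pores:
  reference_count: 4000
  classes:
    - count: 3600
      selects: all
    - count: 400
      selects: [impb, ntf2, cas]
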