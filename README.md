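# KaryoSwitch

Incompletely penetrant phenotypes are a persistent puzzle in cancer cell
biology: clonal populations receiving a uniform stimulus produce a
stereotyped phenotype in only a fraction of cells or multicellular
structures. KaryoSwitch implements a computational toolkit for one
well-characterized instance — ErbB-driven escape of mammary-epithelial 3D
outgrowths from a ductal carcinoma in situ (DCIS)-like state, which
arises in only ~35% of outgrowths despite uniform receptor activation —
and for the hypothesis that the penetrance is set by karyopherin-mediated
nucleocytoplasmic transport of the receptors themselves, with the
exportin CSE1L (CAS) acting as the sensitive node of a toggle-like
circuit.

The package is aimed at systems biologists who want to (i) simulate
karyopherin transport mechanistically, (ii) apply frequency-matching
statistics to single-outgrowth transcriptomic screens of fractional
phenotypes, and (iii) reproduce the bespoke image-quantification
operators used for such systems (circularity, proximity-ligation spot
counting, nuclear/cytoplasmic intensity ratios), all against seeded
synthetic data.

## What is inside

**Transport model.** A three-compartment (cytoplasm, nucleus, nuclear
pore) mass-action model of the Ran GTPase cycle with the classical
import module (importin-α:β cargo loading, RanGTP-driven nuclear
unloading, CAS-mediated importin-α recycling), the CRM1/RanBP3 export
module, and NTF2-mediated RanGDP return. Steady states solve
d**C**/dt = 0 by damped Newton iteration restricted to the stoichiometric
subspace (conserved moieties are exact by construction), with staged
stiff integration (`deSolve::lsoda`) as fallback. The primary readout is
the steady-state nuclear-to-cytoplasmic ratio of total cargo,

N/C = Σ<sub>nucleus</sub> [cargo species] / Σ<sub>cytoplasm</sub> [cargo species],

for classical NLS cargo (binds importin-α:β; K<sub>D</sub> ≈ 32 nM for
the SV40-type NLS, ≈ 2.5 nM for the bipartite Cbp80-type), IBB cargo
(binds importin-β directly, K<sub>D</sub> ≈ 6.5 nM), and optional NES
cargo exported via CRM1:RanBP3:RanGTP.

**Feedback switch.** ErbB heterodimers are modelled as classical cargo
of unknown affinity; two antagonistic proportional feedbacks —
cytoplasmic ErbB → CAS (positive) and nuclear ErbB ⊣ importin-α
(negative, the miR-205–KPNA1 axis) — are co-solved as algebraic
constraints around the steady state. `ultrasensitivityIndex()` quantifies
how switch-like the C/N = (N/C)⁻¹ response to initial CSE1L abundance is
(maximum log–log slope, i.e. apparent Hill coefficient, and 10–90%
transition width).

**Stochastic frequency matching.** For genes flagged as heterogeneous
across n = 20 ten-cell outgrowths (variance-ratio screen against 16
pool-and-split technical controls), events are counted against the
untreated condition's empirical 10th/90th percentiles and the matched
count is compared with the inverse-binomial band B⁻¹₍₂₀,₀.₃₅₎: counts in
the interquartile band [6, 8] are high-priority, in the 90% band [4, 11]
candidates.

**Morphometry.** Object circularity 4πA/P² with a smoothed
boundary-contour perimeter estimator; size-percentile stratification;
Laplacian-of-Gaussian (15 px, σ = 1) spot calling at a 5-photon
threshold with nuclei gated to 100–400 µm²; top-hat background
correction, two-channel quantile normalization and geometric-mean
colocalization for per-cell N/C intensity ratios.

**Synthetic data.** Seeded generators for the expression cohort
(20 + 16 samples per condition, planted heterogeneous and
frequency-matched genes), labelled outgrowth masks with analytically
known circularity, photon-count PLA images, paired-channel cell images,
and per-outgrowth transcript profiles — each serializing its ground
truth.

## Worked example

```r
library(KaryoSwitch)

net <- buildNetwork()                       # reconstructed base model
net
#> ReactionNetwork: 21 species over 52 compartmental states, 108 elementary reactions
#>   compartments: cytoplasm (1200 fL), nucleus (300 fL), pore (30 fL)
#>   pore classes: 1

ss <- steadyState(addCargo(net, cargoSpec("NLS", "classical", 32)))
ss
#> SteadyStateResult: converged (residual 7.58e-15 uM/s, integrate+newton)
#>   N/C ratios:
#>     NLS          24.08
```

The reporter accumulates in the nucleus (N/C ≈ 24 under the shipped
parameterization); the higher-affinity bipartite cargo accumulates
slightly more (N/C ≈ 24.5), and the Ran gradient that powers transport
is steep (nuclear:cytoplasmic free RanGTP ≈ 2.6 × 10³).

```r
# CSE1L suppresses classical cargo accumulation
sensitivityScan(net, "CAS", c(0.5, 1, 2, 4),
                list(cargoSpec("NLS", "classical", 32)))
#>   cargo fold nc_ratio converged
#> 1   NLS  0.5    27.12      TRUE
#> 2   NLS  1.0    24.08      TRUE
#> 3   NLS  2.0    12.88      TRUE
#> 4   NLS  4.0     7.84      TRUE

# frequency matching on a synthetic cohort
se <- genExpressionCohort(cohortSpec(seed = 7))
het <- heterogeneityScreen(se)
calls <- frequencyMatch(se, genes = het$gene[het$flagged])
table(calls$tier)
#>     candidate high_priority     unmatched
#>            39            26            15

binomialBand(20, 0.35)
#> BinomialBand B(20, 0.35): expected 7, IQR [6, 8], 90% CI [4, 11]
```

A matched count of 7 of 20 outgrowths in the high-expression state is
exactly the frequency implied by 35% phenotype penetrance; the tiers
report how compatible each gene's event frequency is with that binomial
expectation.

```r
# the feedback switch: C/N response to CSE1L, with and without feedback
fmOn  <- buildFeedbackModel(net, erbbCargo(320), gainCas = 8, gainImpa = 0.3)
fmOff <- buildFeedbackModel(net, erbbCargo(320), enabled = FALSE)
folds <- 2^seq(-1, 2, length.out = 13)
ultrasensitivityIndex(cnCurve(fmOn, folds))$maxSlope    # ~8.7
ultrasensitivityIndex(cnCurve(fmOff, folds))$maxSlope   # ~3.2
```

With both feedbacks enabled the apparent Hill coefficient of the C/N
response to CSE1L roughly triples — the signature of a switch-like,
toggle-prone circuit.

## Documentation

The methods vignette (`vignettes/karyoswitch-methods.Rmd`) describes the
model structure and its reconstructed parameterization, the statistics,
the numerical methods, what the synthetic generators do and do not
emulate, and known limitations. Function-level documentation lives in
the roxygen comments in `R/`.
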