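---
title: "KaryoSwitch: models, statistics and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KaryoSwitch: models, statistics and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

KaryoSwitch studies how karyopherin-mediated nucleocytoplasmic transport
can set the penetrance of an ErbB-driven epithelial phenotype. This
vignette is the package's own account of what is modelled, which choices
were open and how they were resolved, and what the shipped tests do and
do not establish.

## The transport model

### Structure

The model has three well-mixed compartments — cytoplasm (default
1200 fL), nucleus (300 fL) and nuclear pore (30 fL) — connected only by
first-order translocation steps through the pore compartment. Chemistry
is elementary mass action and lives in the cytoplasm and nucleus; the
pore is a pure conduit. The modules are:

* **Ran cycle.** RCC1-catalysed nucleotide exchange
  (RanGDP → RanGTP) confined to the nucleus; RanGAP hydrolysis, strongly
  stimulated by RanBP1, confined to the cytoplasm; NTF2 shuttles RanGDP
  back into the nucleus. This topology forces the RanGTP gradient that
  powers all directional transport.
* **Import module.** Importin-α:β heterodimer formation, classical
  cargo loading in the cytoplasm, translocation, and RanGTP-driven
  disassembly in the nucleus. IBB-type cargo binds importin-β directly.
* **Recycling module.** CAS (CSE1L) binds RanGTP and exports nuclear
  importin-α; RanBP1 strips the exported complexes in the cytoplasm.
  CAS also binds importin-α without RanGTP (weakly), the competition
  channel by which high CAS suppresses classical import.
* **Export module.** CRM1 binds RanGTP and, via the cofactor RanBP3,
  NES cargo; export complexes are disassembled cytoplasmically. At the
  low base abundance of RanBP3 this pathway is nearly silent, so NES
  and NES-free cargo behave almost identically unless RanBP3 is raised.
* **Passive leak.** Free cargo diffuses slowly through pores
  (0.1 s⁻¹ for reporter-sized cargo, 0.01 s⁻¹ for receptor-sized ErbB
  cargo). The steady-state N/C ratio is the balance between active
  pumping and this leak; with the leak set to zero a cargo without an
  import pathway stays exactly cytoplasmic.

The shipped parameterization is a **reconstruction**: it reproduces the
canonical import/export architecture with rate constants and abundances
in the physiological ranges of the base-model literature, but it is not
a fit to data, and every abundance and rate constant is exposed in
`baseModelConfig()` (or a YAML override via `readModelConfig()`) so that
an alternative table can be dropped in verbatim. The structural
invariants the tests check — moiety conservation, the Ran gradient
direction, steady-state/integration equivalence — hold for any positive
parameterization; the qualitative sensitivity directions additionally
require a parameterization in the physiological regime, as discussed
below.

### Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| Ran total | 15 µM | must exceed total carrier abundance so free nuclear RanGTP saturates carrier binding |
| NTF2 | 6 µM, fast pore transit (10 s⁻¹) | RanGDP return must outpace carrier-mediated RanGTP export, otherwise the gradient collapses when importins are overexpressed |
| Importin-α / β | 4 / 3 µM | with CAS competition, the dimer pool (~2.4 µM) is importin-α-limited, so classical transport rises with importin-α |
| CAS | 3 µM, weak direct importin-α binding (K_D 0.5 µM) | carries both recycling (helps import at low CAS) and competition/RanGTP drain (suppresses import at high CAS) |
| RanBP3 | 0.1 µM | limiting, which keeps the NES pathway nearly silent at base |
| empty importin-β pore rate | 0.1 s⁻¹ | cargo-free importin-β shuttling is a futile RanGTP drain; throttling it reflects its low FG-repeat engagement without cargo |
| cargo k_on | 1 µM⁻¹s⁻¹ | only K_D values are known; k_off = K_D·k_on |
| passive cargo leak | 0.1 s⁻¹ (reporters), 0.01 s⁻¹ (ErbB) | sets the N/C scale; receptor complexes are much larger than GFP-tandem reporters |

### Numerical methods

The state is the vector of species *amounts* (concentration × volume),
which makes every conserved moiety an exact linear invariant of the
stoichiometry. Steady states are found by damped Newton iteration on the
reduced coordinates of the stoichiometric image space (an orthonormal
basis of col S from a QR decomposition), so Newton steps cannot leave
the conservation manifold; from poor starting points the solver first
integrates with `lsoda` (analytic Jacobian) in stages of 10³–10⁶ s and
then refines. Convergence is declared at max |dC/dt| < 10⁻⁹ µM/s, and a
non-converged solve is returned flagged, never silently. Warm starts
across parameter changes are projected back onto the new conservation
totals by adjusting each moiety's largest free pool (falling back to a
cold start if that would go negative).

The N/C ratio counts total cargo (free plus every cargo-containing
complex) per compartment and excludes the pore, matching what an
immunofluorescence readout of total reporter sees.

### Sensitivity scans and their range

`sensitivityScan()` defaults to 0.5–2-fold perturbations, the range of
outgrowth-to-outgrowth transcript variation that the stratified analyses
address (the acceptance checks use 0.5–4-fold where the behaviour
remains monotone). Outside that window the reconstruction enters regimes
where some directions invert — e.g. below ~0.4-fold CAS, recycling
rather than competition limits classical import, and several-fold
importin-β overexpression drains the Ran gradient through futile
carrier cycling. These saturation behaviours are physiologically
sensible but outside the scope of the qualitative claims the package
reproduces, and the documented scan ranges reflect that.

The two-pore-class configuration (a 3600-pore general class plus a
400-pore class selective for the import machinery) changes steady-state
N/C of admitted cargo by < 1%: with thousands of pores the selective
class is a minor fraction of total conductance. A cargo *excluded* from
a large selective class is, by the same arithmetic, not neutral — the
partition is configurable and this limitation is intentional.

## The ErbB feedback switch

Internalized ErbB heterodimers are classical cargo with unknown
importin-α:β affinity. Two steady-state algebraic constraints couple the
cargo's distribution back to the machinery:

* CAS_eff = CAS₀ · (1 + g_CAS · f_c), with f_c the cytoplasmic amount
  fraction of ErbB (positive feedback: cytoplasmic ErbB induces CSE1L);
* Impα_eff = Impα₀ · max(0, 1 − g_α · f_n), with f_n the nuclear
  fraction (negative feedback: nuclear ErbB represses KPNA1 via
  miR-205).

The coupled system is solved as a fixed point over the two effective
scales wrapped around the transport steady state (secant-accelerated
damped iteration, relative tolerance 10⁻⁶, maximum 200 iterations).
`cnCurve()` continues the solution from both ends of the CSE1L grid;
when the branches separate by more than a relative tolerance the curve
is reported with both branches — bistability is a result, not an error.

Choices that were genuinely open:

* **Functional form.** "Proportional" feedback is implemented as the
  linear effective-abundance constraints above. Any saturating variant
  must preserve the reduction property (gains → 0 recovers the base
  model exactly, which the tests verify to 10⁻⁶) and the qualitative
  orderings.
* **Gains.** Unknown; defaults g_CAS = 8, g_α = 0.3 put the model in a
  monostable-ultrasensitive regime where enabling feedback roughly
  triples the maximum log–log slope of C/N versus CSE1L, with mild
  bistability appearing toward the weak-affinity end of the ladder.
* **Sensing.** By default the CAS loop senses all cytoplasmic ErbB; an
  alternative mode senses only the free, carrier-unbound (hence
  signalling-competent) pool.
* **Affinity ladder.** The strong/medium/weak ladder ships as
  {320, 1000, 3200} nM. With the reconstructed importin dimer pool at
  ~2.4 µM, nanomolar affinities are all loading-saturated and an
  affinity ladder confined there cannot modulate transport at all; the
  ladder must straddle the saturation knee (K_D approaching the dimer
  concentration) for affinity to matter, which is also the regime where
  ultrasensitivity declines monotonically from strong to weak binding.
  A tripartite juxtamembrane NLS is moreover expected to be
  substantially weaker than the optimized monopartite/bipartite
  reporter NLSs.

`ultrasensitivityIndex()` computes the maximum local log–log slope by
central differences and the 10–90% transition width from interpolated
crossings; a non-monotone curve is isotonic-fitted first and flagged.

## Stochastic frequency matching

The heterogeneity screen is a documented simplified surrogate for full
stochastic-profiling filtering: genes detected in at least half the
samples are tested by a one-sided variance-ratio test of the biological
(10-cell outgrowth) variance against the larger of the pool-and-split
technical variance and a coefficient-of-variation floor
((log₂(1 + 0.2))² on the log₂ scale), with Benjamini–Hochberg control at
FDR 0.1. Pool-and-split profiles whose fold-range exceeds 5 are excluded
as irreproducible, and technical variances significantly above the floor
(χ² test at BH FDR 0.05) replace it as the reference. The parameter set
(detection P = 0.1, max fold-change 5, FDR 0.05/0.1, reference CV 0.2)
is exposed so the full published pipeline can be substituted.

Event counting uses the untreated condition's per-gene empirical
10th/90th percentiles (type-7 linear interpolation between order
statistics; for values 1..20 these are 2.9 and 18.1) as thresholds, with
strict inequalities so threshold ties are not events — the conservative
convention. The matched count is max(events above, events below) by
default, avoiding double-counting of bidirectional genes; a "sum" mode
is available. The count is compared with the inverse-binomial band at
the phenotype penetrance: for B(20, 0.35) the expectation is 7, the
interquartile band [6, 8] (high-priority) and the 90% band [4, 11]
(candidates), all obtained by exact summation of the probability mass
function. Classification is invariant under any monotone transformation
applied jointly to values and thresholds.

Penetrance proportions are variance-stabilized as arcsin√p before
mean ± s.e. summaries and two-sided t tests.

## Morphometry

**Circularity** is 4πA/P². Digital perimeters are delicate: Crofton-type
estimators are accurate for isotropic shapes but under-measure
axis-aligned rectangles, while raw boundary-chain lengths over-measure
staircased circles. The package traces the Moore boundary contour,
smooths it with a circular moving average (window 3) and measures the
closed polygon — rasterized discs of radius 25–100 px measure within
[0.996, 1.017] and a filled square at 0.810 versus π/4 ≈ 0.785, inside
the documented digital tolerance δ = 0.05 (so circularity ≤ 1.05).
Size stratification keeps objects at or above the (100 − 35)th area
percentile, ties included.

**PLA spot calling** convolves the photon-count image with a 15 × 15,
σ = 1 px rotationally symmetric Laplacian-of-Gaussian kernel
(zero-mean, so any uniform background is annihilated), thresholds the
negated response at 5 photons/pixel, and collapses each connected
component to one spot at its response maximum. Spots are assigned to the
nearest nucleus by centroid distance with no distance cap (optional);
nuclei outside 100–400 µm² are dropped together with their assigned
spots.

**N/C intensity** background-corrects each channel with a morphological
top-hat (disc radius 25 px, larger than the cells so cell-scale signal
is preserved), quantile-normalizes the two channels to their average
sorted profile, combines them by pixel-wise geometric mean, and reports
per cell the mean colocalized intensity inside the nuclear mask over the
mean in the cytoplasmic remainder. Swapping channels is exactly
symmetric; global rescaling of one channel is neutralized by the
quantile step up to the (slight) shift of the shared target profile.

## Synthetic data: what it emulates, and what it does not

The cohort generator mirrors the study design constants — 20 biological
ten-cell outgrowths plus 16 pool-and-split equivalents per condition, a
35% high-state frequency for frequency-matched genes in the treated
condition and a 10% background rate in the untreated condition (the
background that motivates the 10th/90th percentile thresholds), ~1000
genes by default with a log₂ high-state shift of 3. Distributional
choices (lognormal baselines, Gaussian biological/technical noise at
log₂ sd 0.25/0.2, uniform detection dropout) are invented stand-ins.
Passing the recovery tests therefore shows the statistic behaves
correctly under its own assumptions — two-state mixtures over a
unimodal background — not that real microarray noise (probe effects,
intensity-dependent variance, batch structure) is handled; the screen is
deliberately swappable for the full published pipeline.

Image generators place geometric primitives (disc unions with analytic
area/perimeter; elliptical nuclei spanning the area gate; Gaussian
photon peaks over Poisson background validated to stay below the LoG
threshold) on regular grids with spacings that prevent collisions; real
micrograph segmentation is out of scope. Every generator is a pure
function of its specification and seed and serializes its ground truth.

Problem sizes used by the shipped tests and the acceptance script —
1000-gene cohorts over 10 seeds, 20 jittered model configurations for
the steady-state/integration equivalence, 13-point switch curves, 5-point
sensitivity grids — were chosen so the full analysis replays in a few
minutes on a single core while keeping every estimate's sampling error
well inside its test tolerance.

## Known limitations

* The rate table is a reconstruction; absolute N/C magnitudes (~24 for
  reporters under the defaults) are not calibrated to measured reporter
  ratios, and only ordering/direction claims are tested.
* Sensitivity directions are established on 0.5–4-fold grids; far
  outside that range the model's saturation regimes invert some of
  them.
* The NES/export module is RanBP3-gated only; direct CRM1–cargo binding
  without RanBP3 is omitted.
* The heterogeneity screen is a surrogate, not the published
  stochastic-profiling filter.
* The feedback is a steady-state constraint; no kinetics of CSE1L
  induction or miR-205 maturation are modelled, so the package makes no
  claims about transition times between states.
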