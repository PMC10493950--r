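---
title: "Methods: hydraulic trait extraction and phylogenetic comparative analysis"
author: "hydrophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydraulic trait extraction and phylogenetic comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrophylo)
```

This vignette is the package's account of its methods: the models and
procedures implemented, the tunable parameters and why their defaults are
what they are, what the synthetic-data generators do and do not emulate,
and the numerical and design choices made where the underlying measurement
protocols leave the procedure open.

## 1. The optical vulnerability stage

### Model

During bench dehydration of a leaf, cavitation events in the vein network
appear as sudden, localized, persistent changes in transmitted-light
intensity. The pipeline treats a stack of grayscale frames (every 3 min)
plus a psychrometer water-potential trace (every 10 min) as inputs and
computes:

1. `differenceStack()`: pixels with `|frame_{k+1} − frame_k| >`
   `diffThreshold` are event candidates, attributed to the later frame.
   Intensities are doubles in [0, 1], so the subtraction happens in a
   signed domain — there is no unsigned wraparound.
2. `filterNoise()`: connected components (8-connectivity) smaller than
   `minEventPx` are removed. This is the artifact filter: genuine embolism
   events are extended patches along veins, while slow leaf shrinkage
   produces scattered, small, transient intensity flickers. An optional
   region mask restricts analysis, e.g. to a vein mask.
3. `cumulativeEmbolism()` / `vulnerabilityCurve()`: the running sum of
   retained pixels, as a percentage of the final total (the area at
   complete dehydration), against water potential interpolated linearly at
   each frame time (`assignPsi()`; frames outside the trace span are
   clamped to the nearest endpoint with a warning).
4. `psiAtEmbolism()`: P50 is the water potential at the first 50% crossing,
   linearly interpolated between the bracketing frames, walking the curve
   in dehydration order. A logistic-fit alternative
   (`psiAtEmbolismLogistic()`) exists for sensitivity analysis; the
   empirical crossing is the default because the curve itself, not a
   parametric form, defines the trait.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `diffThreshold` | 0.15 | intensity | ≈ 40% of the simulated event amplitude (0.35) and > 5 sd of the default frame noise, so false positives are negligible while no true event is missed |
| `minEventPx` | 4 | px | smallest simulated event is 4 px; shrinkage flickers are single pixels |

Both are exposed because the corresponding acquisition-side quantities
(camera gain, optics, vein calibre) vary between rigs; the defaults are
calibrated on the simulator, and the noiseless closed loop is
threshold-insensitive across 1–50% of the event amplitude (a test asserts
this).

### What the simulator emulates

`simulateDrydownImages()` builds a stack in which water potential declines
linearly in time, and a pool of embolizable pixels is partitioned into
`nEvents` connected patches. Each patch brightens at the frame where psi
crosses its threshold and stays bright; thresholds are set by inverting the
logistic `F(psi) = 100 / (1 + exp(slope/25 · (psi − p50)))` at the midpoint
of each event's cumulative-area interval, so the cumulative curve follows a
known logistic with `F(p50) = 50` exactly. Gaussian intensity noise and
single-pixel one-frame flickers ("shrinkage") complete the picture. The
generator does **not** emulate camera optics, vein architecture, image
drift/registration error, or spatially correlated shrinkage; a pass of the
closed-loop tests therefore shows the *computational* pipeline is correct
and noise-robust, not that it would survive, say, unregistered frame
drift — registration is out of scope.

The logistic form is a modelling choice of the generator (the analysis
pipeline fits no sigmoid); it was chosen so that the true P50 is an
explicit parameter, with the slope expressed in % per MPa at the midpoint.

## 2. The minimum-conductance stage

### Model

A detached branchlet in a drying oven loses water through a conductance
that relaxes from its initial (partly stomatal) value to the cuticular
minimum. From a mass series at temperature T and relative humidity RH:

* `detectSteadyState()` finds the terminal window where the rolling
  least-squares slope (windows of `window = 5` points) stays within
  `relTol = 0.15` (relative) of the final window's slope. The run must
  contain at least two qualifying windows; a series still curving at its
  end raises a "no steady state" error. The measurement protocol does not
  state a criterion; rolling-slope agreement with the terminal rate is the
  smallest assumption that excludes the stomatal phase.
* `transpirationRate()` computes `R = Δw/(Δt·A)` as the least-squares
  slope of mass on time over that window — regression rather than
  first-vs-last differencing, for noise robustness — converted to
  mmol m⁻² s⁻¹ via the molar mass of water (18.015 g mol⁻¹), sign-flipped
  so mass loss gives R ≥ 0.
* `leafArea()`: area = dry mass (kg) × SLA, doubled by default. SLA is
  conventionally projected (one-sided) while the transpiring surface is
  double-sided; whether a given study's SLA convention already includes
  both sides is often ambiguous, so `doubleSided` is an explicit flag
  rather than a guess.
* `gminAtTemperature()` applies `g = R / VPD × P_atm` with
  `SVP = (610.7·10^(7.5T/(237.3+T)))/1000` (Buck), `VPD = (1−RH/100)·SVP`,
  and `P_atm = 101.6` kPa. The 101.6 value (rather than the standard
  atmosphere 101.325) is the constant conventionally used in this assay's
  conductance equation and is kept for comparability; it is configurable.

### The phase-transition temperature

`fitBreakpoint()` fits the continuous two-segment model
`g(T) = b0 + b1·T + b2·(T − ψ)₊` by exhaustive search of ψ on a 0.1 °C
grid strictly between the 2nd and penultimate observed temperatures
(each candidate is a 3-column linear least-squares fit), followed by
golden-section refinement around the best grid point. T_P is ψ. With only
~7 temperature points, grid + refinement is both exact within model class
(a noiseless two-segment input is recovered to ±0.05 °C; a test asserts
this) and immune to the local-optimum failures of derivative-based
breakpoint estimators at this n. If the SSE profile is flat across the
whole grid (relative range ≤ 1e−8), the data are effectively linear and
the breakpoint is declared unidentifiable rather than returning an
arbitrary interior point.

T_P is fit to the species-mean g per temperature (replicates averaged
first), which is why it carries no standard error; per-replicate fitting
is available via `speciesTp(..., perReplicate = TRUE)`.

### What the simulator emulates

`simulateMassSeries()` integrates
`g(t) = gmin(T) + (g0 − gmin(T))·e^{−t/τ}` analytically — stomatal closure
as a single exponential, because only the terminal steady state matters
downstream — with `gmin(T)` piecewise linear around a known breakpoint,
and adds Gaussian mass noise (default 0.5 mg, matching a 0.1 mg-resolution
balance plus handling error). Boundary-layer effects, humidity-sensor
error structure, and water depletion of the tissue are not modelled.

## 3. The comparative stage

### Phylogenetic signal

With `V` the Brownian covariance of the (rooted, branch-length) tree and
`V(λ)` multiplying its off-diagonals by λ:

* `blombergK()` implements the ratio-of-MSE statistic with the
  phylogenetically corrected mean `â = (1ᵀV⁻¹1)⁻¹1ᵀV⁻¹y` and the
  Brownian expectation term `(tr(V) − n/(1ᵀV⁻¹1))/(n−1)`; K ≈ 1 under
  Brownian motion, → 0 for phylogeny-free data. Significance comes from a
  tip-permutation test, `p = (1 + #{K_perm ≥ K_obs})/(nPerm + 1)`.
* `pagelLambda()` maximizes the profile log-likelihood of the single-mean
  model with covariance σ²V(λ) over λ ∈ [0, 1] (mean and σ² profiled
  analytically; `optimize()` with tolerance 1e−6; both boundaries checked
  explicitly since the profile can be monotone). The LRT against λ = 0
  uses the χ²₁ reference, which is conservative at the boundary — noted
  here deliberately: reported λ p-values err on the side of not declaring
  signal.

λ is restricted to [0, 1]: on an ultrametric depth-normalized tree this is
the range in which V(λ) is guaranteed positive definite and the parameter
retains its interpretation as a branch-length transformation.

### PGLS, R², and influence

`pglsFit()` estimates `β̂ = (XᵀV(λ)⁻¹X)⁻¹XᵀV(λ)⁻¹y` with λ by ML on the
same profile likelihood (or fixed). Standard errors use
`σ̂²(XᵀV⁻¹X)⁻¹` with `σ̂² = RSS_V/(n−p)`; p-values are two-sided t with
n − p df. Species present in only one of tree and table, or with missing
values in model variables, are dropped jointly with a warning.

R² is GLS-based: `1 − RSS_V/TSS_V`, with TSS from the GLS intercept-only
fit under the *same* V(λ). Other R² flavours exist for PGLS (OLS-scale,
adjusted, likelihood-based); the GLS definition is used because it is the
one for which the nesting argument (model SSE ≤ intercept-only SSE under
the same covariance) holds exactly. Comparisons with R² values computed
under other conventions should be made cautiously.

Cook's distance is computed on the whitened regression — y and X
premultiplied by V(λ)^{−1/2} — using the textbook leverage/residual
formula there, because influence on GLS coefficients is what the
decorrelated problem measures; at λ = 0 this reduces exactly to OLS
Cook's distance (a test asserts agreement to 1e−10). The influence cutoff
is the common 4/n rule, configurable; flagged species are refit-excluded
and both fits are reported. If excluding a flagged species empties one
subgenus, the subgenus indicator is dropped from the refit formula.

### Climate PCA, correlation, smoothing, multiplicity

`climatePCA()` standardizes by default (the climate variables mix °C and
mm; a covariance-matrix PCA would be dominated by precipitation's
numeric range). The PC1 sign is fixed so its loading on the
coldest-month minimum temperature is positive — larger PC1 = warmer/drier
— a pure orientation convention that makes signs comparable across runs.
`loessSmooth()` is local-linear (degree 1) with tricube weights via
`stats::loess` with a direct surface; spans above 1 (the default here is
1.5) enlarge the bandwidth beyond the data range in the conventional way,
giving the near-global smooth appropriate for visualizing a broad,
possibly non-monotone trait–climate trend. `bonferroniAdjust()` is
`min(1, p·m)` with an explicit declared family size m; the pipeline's
family is the two P50 climate regressions (PC1 and coldest-month minimum
temperature), so m = 2.

## 4. The synthetic comparative generators

`simulatePhylogeny()` draws a pure-birth tree and rescales depth to 1;
trait scales are arbitrary units, so a unit-depth tree loses nothing and
makes λ and rate parameters comparable across runs. `simulateTraitsBM()`
draws one multivariate-normal sample with covariance σ²V(λ) via Cholesky.
`simulateClimate()` draws multivariate-normal sites under a target
correlation matrix and affinely rescales columns to realistic
cool-temperate spans (annual means 6–12 °C, annual precipitation
600–1500 mm, warmest-month maxima near 14–22 °C, coldest-month minima
−3–4 °C, driest-quarter precipitation 120–260 mm); the default
correlation matrix encodes one dominant warm/dry-vs-cool/wet axis
(population PC1 share ≈ 87%), the structure under which using PC1 as the
climate predictor is sensible. `simulateTraitClimate()` composes these
into `trait = β0 + β1·PC1 + β2·subgenus + ε`, `ε ~ N(0, σ²V(λ_resid))`,
with the subgenus indicator taken from the root bipartition of the tree —
mirroring a two-subgenus sampling design.

## 5. The pipeline fixture and its conditions

`runPipeline(list(seed = ...))` simulates a 14-species study end to end
and analyzes it exactly as real data would be. The fixture's conditions
are fixed design choices, stated here:

* **Residual phylogenetic signal λ_resid = 0.2.** The fixture models a
  clade whose hydraulic traits carry little phylogenetic signal — the
  regime hydraulic-trait surveys of closely related congeners typically
  report. It also matters technically: at
  n = 14 the ML λ̂ is noisy, and when residual signal is strong the
  boundary estimate λ̂ = 1 makes the whitening absorb deviations carried
  by long terminal branches, degrading outlier detectability.
* **Planted outlier.** One species — the one at the coolest/wettest end of
  the climate axis — has its true g_min lowered by 4 mmol m⁻² s⁻¹,
  matching the magnitude by which the most frost-tolerant species in the
  packaged table undershoots climatically comparable species (≈ 4 vs
  8–10). The pipeline must flag it by Cook's distance and refit without
  it.
* **Balanced subgenus split.** Simulated trees are redrawn
  (deterministically, by advancing a derived seed) until each side of the
  root bipartition has ≥ 4 tips, mirroring the 8/6 two-subgenus design. A
  singleton "subgenus" would make the indicator a per-species dummy with
  leverage exactly 1, for which Cook's distance is degenerate.
* **Problem sizes.** Default per-species raw data are two 64×64-px,
  120-frame stacks and two 7-temperature drydown series of 37 points —
  sizes chosen so a full simulated study runs in seconds while leaving
  every estimator comfortably inside its accuracy envelope (the
  acceptance checks use 128×128, 200-frame stacks for the P50 loop). The
  trait models are `p50 = −4.8 + 0.25·PC1 + 0.2·I + ε`,
  `gmin = 6.5 − 0.8·PC1 + 0.5·I + ε`, `tp = 36 + 0.2·PC1 + ε` — a mild
  positive P50 trend, a clearly negative g_min trend (the planted effect
  the pipeline must recover), and a breakpoint near the middle of the
  assay range.

The report is a pure function of the configuration: every random draw
derives from the master seed, and the report carries an MD5 hash of its
numerical content, so two runs with the same config are hash-identical.

## 6. Numerical choices and degenerate inputs

* Covariance factorizations use Cholesky throughout; V(λ) on a valid tree
  with λ ∈ [0, 1] is positive definite, and a failed factorization is
  surfaced as an error rather than silently regularized.
* `optimize()` tolerances are 1e−6 for λ (both in signal testing and
  PGLS) and for the breakpoint refinement.
* Ties/edge cases: a frame time exactly at a trace sample returns that
  sample's psi; a curve point exactly at the requested percentage returns
  that frame's psi; `speciesP50()` reports SE as missing for n = 1;
  `transpirationRate()` returns 0 with a warning for a non-negative mass
  slope; `cumulativeEmbolism()` returns all-zero percentages with a
  completeness warning when nothing was detected, and `psiAtEmbolism()`
  refuses incomplete curves.
* Constant traits, zero-variance climate columns under standardization,
  collinear designs (reported with the offending column names), RH = 100%
  (zero VPD), and unrooted trees are all rejected with specific errors.

## 7. Known limitations

* No image registration: frame drift would masquerade as widespread
  change; stacks are assumed aligned.
* The steady-state detector assumes the series *ends* in the steady
  phase; drydowns truncated mid-closure error out rather than
  extrapolating.
* The λ LRT's χ²₁ reference is conservative at the boundary; permutation
  p-values for K are exact-conservative by construction.
* GLS R² and Cook's distance conventions are one defensible choice among
  several (see §3); cross-study comparisons of those quantities should
  check conventions.
* The generators produce Gaussian noise only; heavy-tailed sensor error,
  drift, and autocorrelated humidity fluctuations are not modelled, so
  recovery results bound performance under idealized noise.
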