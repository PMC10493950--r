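# hydrophylo

Leaf hydraulic traits from raw measurement series, and their climate
correlates across species on a phylogeny.

Plants under drought close their stomata, but water keeps leaking through
the cuticle; embolisms spread through the leaf xylem as water potential
falls. Three traits summarize how a species copes:

* **P50** — the water potential (MPa) at which 50% of cumulative leaf-xylem
  embolism has occurred, read from an optical vulnerability curve;
* **g_min** — the minimum shoot conductance to water vapour
  (mmol m⁻² s⁻¹) after stomatal closure, estimated from branch drydown
  mass series;
* **T_P** — the phase-transition temperature (°C) at which g_min, roughly
  flat at low temperature, starts rising steeply, estimated as a breakpoint
  in g_min vs temperature.

`hydrophylo` implements the full path from raw inputs (time-lapse image
stacks plus a psychrometer water-potential trace; drydown mass series with
temperature/humidity metadata) to these traits, and the comparative layer
that relates them to climate across species: climate PCA, phylogenetic
signal (Blomberg's K with a permutation test, Pagel's λ by ML), PGLS with
ML λ and Cook's-distance influence screening, Pearson correlation,
Bonferroni correction, and Loess smoothing. Because raw field data of this
kind are rarely deposited, the package ships a synthetic-data generator
that produces every input with known ground truth, so each stage is
testable by closed-loop parameter recovery.

## The core computations

**Optical vulnerability.** Consecutive frames are differenced; pixels whose
absolute intensity change exceeds a threshold are cavitation-event
candidates. Connected components (8-connectivity) smaller than a minimum
area are discarded as leaf-shrinkage artifacts. The cumulative retained
area, expressed as a percentage of the total at complete dehydration and
plotted against water potential (interpolated from the psychrometer trace
at each frame time), is the vulnerability curve; P50 is the water potential
at the first 50% crossing, linearly interpolated.

**Minimum conductance.** Over the terminal steady-state window of a drydown
(found by rolling-slope comparison), the transpiration rate is

```
R = Δw / (Δt · A)            [mmol m⁻² s⁻¹, via the molar mass of water]
```

with A the double-sided leaf area from dry mass × SLA. Conductance follows

```
SVP = (610.7 · 10^(7.5·T/(237.3+T))) / 1000     [kPa, Buck equation]
VPD = (1 − RH/100) · SVP                        [kPa]
g   = R / VPD · 101.6                           [mmol m⁻² s⁻¹]
```

with 101.6 kPa sea-level atmospheric pressure. Species-mean g at each assay
temperature (25–48 °C) is fit with a continuous two-segment linear model
`g(T) = b0 + b1·T + b2·(T − T_P)₊`; the breakpoint, found by an exhaustive
0.1 °C grid plus golden-section refinement, is T_P.

**Comparative statistics.** With V the Brownian covariance of the tree and
V(λ) its off-diagonal-scaled version, Blomberg's K is the
(MSE₀/MSE)-ratio statistic standardized by its Brownian expectation, Pagel's
λ maximizes the profile likelihood of the single-mean Brownian model over
[0, 1], and PGLS solves `β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y` with λ estimated by ML.
Cook's distances come from the whitened regression (equal to the textbook
OLS formula at λ = 0); species exceeding 4/n are refit-excluded.

## Worked example

```r
library(hydrophylo)

## simulate a drydown image stack with known P50 and recover it
sim <- simulateDrydownImages(p50 = -4.8, seed = 7)
res <- opticalP50(sim$stack, sim$trace)
res$curve
#> VulnerabilityCurve: 200 frames, psi -0.50..-8.00 MPa, complete: TRUE
sprintf("P50 estimate: %.3f MPa", res$p50)
#> "P50 estimate: -4.796 MPa"     # truth was -4.8

## drydown mass series at seven temperatures -> g_min(T) -> T_P
dry <- simulateMassSeries(seed = 7)        # true g_min(25) = 5, T_P = 36
pts <- lapply(dry$series, gminAtTemperature)
pts[["25"]]
#> ConductancePoint: T = 25.0 C, gmin = 5.073 mmol m-2 s-1 (VPD 1.900 kPa)
speciesTp(pts)
#> BreakpointFit: T_P = 36.05 C, slopes 0.0524 / 0.6098, SSE = 0.0003272

## climate PCA of the packaged 14-species table
pca <- climatePCA(eucalyptTraits())
pca
#> ClimatePCA: 3 variables, PC1 explains 90.9% of variance
```

The recovered P50 sits within one frame's water-potential step of the truth,
g_min within a few percent, and the breakpoint within a tenth of a degree —
the closed-loop accuracy the test suite checks systematically. The PCA of
the packaged table's three site-climate variables (warmest-month maximum,
coldest-month minimum, driest-quarter precipitation) is dominated by one
warm/dry-vs-cool/wet axis.

The full pipeline — simulate raw inputs for 14 species, extract all three
traits, run every comparative analysis, and write a hashed, reproducible
report — is one call:

```r
report <- runPipeline(list(seed = 1, outDir = "out"))
```

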