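---
title: "Models and methods: edges, corridors, and bee community distance decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: edges, corridors, and bee community distance decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`beecorridors` analyses the two complementary roles that seminatural linear
landscape structures (LLS) — the edge zones around forest, low woody
vegetation, permanent grassland and sparsely vegetated patches — can play
for wild bees in intensively managed landscapes: providing habitat, and
providing dispersal corridors. This vignette is the package's own account
of the models it fits, the assumptions behind them, and the choices made
where the design was genuinely open.

```{r setup}
library(beecorridors)
```

## Edge extraction from a categorical raster

A land-cover raster (10-m class-coded cells; the coding follows the
11-class convention returned by `landcover_codes()`) is the sole spatial
input. `extract_boundaries()` polygonizes each class group *separately*
(forest {2, 3}, low woody {5}, herbaceous {6}, sparse {9}) and emits one
unit segment per boundary face — a cell edge between a cell inside and a
cell outside the group. Three conventions matter and are fixed here:

* **Raster-border faces are not edges.** A patch truncated by the study
  area boundary contributes no segment there. Including them would
  fabricate corridors along the raster frame; a map boundary is an
  artefact of the extent, not a habitat edge.
* **Separate polygonization, then union with deduplication.** A
  forest–grassland face belongs to both groups' boundaries; it is one
  physical edge and is counted once. The alternative — merging the four
  groups into a single seminatural mask before tracing — would *erase*
  internal edges such as a forest–grassland transition entirely, which
  contradicts their ecological role, so the separate-then-union rule was
  adopted.
* **Closed-cell rasterization.** `rasterize_lines()` marks a cell when a
  segment touches its closed square, so a segment lying exactly on a
  shared cell edge marks both neighbours and a corner touch marks all
  four cells at the corner. This is orientation-free and deterministic:
  re-ordering segments can never change the result.

Forest-only boundaries use group {2, 3}; nonforest LLS length is the
difference of totals, floored at zero. Aggregation to the corridor grid
(`aggregate_proportion()`, default factor 10, i.e. 100-m cells) divides
block counts by factor², zero-padding grids whose dimensions are not
divisible (padding adds no 1-cells, so the count of fine edge cells is
conserved exactly — a property the test suite asserts rather than assumes).

Per-site covariates use exact geometry: `length_within_radius()` clips each
segment to the closed disc by solving the segment–circle quadratic, and
`grassland_proportion()` counts cell centres in the disc (at 10-m
resolution, centre counting is an unbiased and much cheaper alternative to
area weighting).

## Species richness models across spatial scales

For radii of 250–1500 m (250-m steps, spanning typical bee foraging
ranges) the package fits Poisson GLMs (log link) of site-level bee species
richness:

```
richness ~ log(LLS_r + 1) + plant_richness + log(grassland_r + 1e-4)
           + country + x + y
```

Plant richness controls local habitat quality, grassland cover controls
surrounding habitat availability, country absorbs regional differences,
and the raw projected coordinates guard against residual spatial trends.
Two numerical guards are needed because lengths and proportions can be
exactly zero: lengths enter as `log(m + 1)` (one metre is negligible
against the 10⁴–10⁶ m totals involved) and proportions as `log(p + 1e-4)`
(one percent of the smallest nonzero value possible at 100-m resolution).
Coordinates are centred and scaled; this changes coefficients of x and y
but no deviance, AICc difference, or test involving other terms.

Models are compared by AICc (`aicc_value()`, the k(k+1)/(n−k−1) correction
matters at n ≈ 40–70 sites); `select_radius()` takes the minimum per LLS
type, resolving ties toward the smaller radius (the more conservative
spatial claim). Diagnostics replace simulation-based residual tools with
two direct checks: the Pearson dispersion ratio χ²/(n−k) (flagged above
1.5) and Moran's I on Pearson residuals with inverse-distance,
row-normalized weights (the weighting most commonly used with the
cited implementation; the expectation −1/(n−1) and a two-sided normal
approximation give the p-value). Significance of the LLS term uses
drop-one likelihood-ratio tests, which for Poisson GLMs equal deviance
differences — an identity the tests exploit as an oracle.

## Conductance surfaces and least-cost corridors

The 100-m proportion grid x (share of 10-m edge cells) is read as a
conductance surface: movement is easy where edge density is high. Between
8-neighbouring cells i, j the conductance is `mean(x_i, x_j) / d_ij` with
d in cell units (1 rook, √2 diagonal) and the traversal cost its
reciprocal — the 1/x transform, under which cost grows steeply (though
hyperbolically, not literally exponentially) as edge density falls. The
arithmetic mean is the convention of grid-graph conductance constructors;
a geometric mean was rejected because a single zero cell would annihilate
any edge touching it.

Zero proportions make 1/x undefined, so cell values are floored at
ε = 10⁻⁶ before averaging. The floor keeps the graph connected and makes
crossing empty matrix roughly 10⁶ times costlier than following dense
edges, so any positive-density detour is preferred; results are
insensitive to ε across several orders of magnitude because paths through
empty matrix are chosen only when no alternative exists.

Paths are computed by Dijkstra's algorithm (compiled; nodes in row-major
order) with a fixed tie-break — among equal-cost relaxations the lowest
row-major predecessor wins, and equal-distance queue pops resolve by node
index — so corridor outputs are bit-reproducible. Sites snap to their
containing coarse cell; reported lengths are centre-to-centre polyline
lengths (≤ one cell diagonal of discretization error), and the movement
cost of a path is Σ(1−x) over its cells, endpoints included, each visited
cell counted once. Pair tables are restricted to within-country pairs,
because cross-country comparisons would conflate landscape permeability
with regional species-pool differences.

## Community similarity and distance decay

Occurrence tables are curated before analysis: kleptoparasitic species are
removed (their distribution tracks hosts, not habitat), and cryptic
complexes — morphologically inseparable species groups such as the
*Bombus sensu stricto* subgenus — are pooled into one morphospecies by
summing columns. Compositional similarity is binary Bray–Curtis,
`1 − (A+B−2J)/(A+B) = 2J/(A+B)` for presence–absence richnesses A, B and
shared count J. For the sparse solitary-bee subsets a dummy species
present everywhere is added (A, B, J each + 1), which keeps the index
defined for empty communities and damps zero inflation; whole-community
and plant similarities are computed without it, following the source
convention of applying the dummy only where sparsity demands it. A pair
whose similarity is undefined (both communities empty, no dummy)
propagates as missing and is dropped from model fits with a message,
never silently coerced to zero.

The decay model is a crossed-random-intercept mixed model per country:

```
similarity_ij ~ distance_ij + plantSR_i × plantSR_j + plant_sim_ij
                + (1|site_i) + (1|site_j)
```

with `distance_ij` one of: geographic distance, LCP length or LCP cost on
either edge map — or absent (the null model). The crossed intercepts
absorb site-specific mean similarity (each site enters many pairs); the
plant terms control for habitat-quality confounding. Fitting uses maximum
likelihood via `glmmTMB` with Gaussian or Student-t responses (the heavy
tails accommodate boundary-inflated similarities); the Student-t degrees
of freedom are estimated. The AICc parameter count is the full count —
fixed effects, two random-intercept variances, the residual scale, and
the t df where applicable — a convention that must be stated because AICc
differences depend on it. A `family = "auto"` probe selects between the
two families by AICc on the geographic-distance fit, a pragmatic
counterpart to residual-based family checks. Quadratic distance terms use
orthogonal polynomials; raw km² regressors are poorly conditioned.

Because similarity can *rise* again at large separations (spatially
clustered land-use supports similar pools), `threshold_sensitivity()`
fits linear and quadratic distance models on subsets truncated at 10–105
km (5-km steps) and records ΔAICc = AICc(linear) − AICc(quadratic);
the retained maximum distance is the largest threshold at which the
linear model wins (ΔAICc < 0) or is indistinguishable (|ΔAICc| < 2) —
keeping as much data as possible while the decay is monotone. Thresholds
with fewer than 30 pairs are skipped, and nested subsets of identical
size reuse the previous fit.

## The synthetic scenario generator

`generate_scenario()` is first-class, tested code, not a fixture. It
emulates the study conditions end to end: a 1000 × 1000-cell 10-m raster
(10 × 10 km) classified from a box-smoothed Gaussian field, so classes
form contiguous patches and edges form connected networks; 20 + 20 sites
in spatially split "west"/"east" countries, rejection-sampled to ≥ 1 km
separation; 40 plant species with Euclidean occupancy decay; and 79
nonparasitic bee species (15 bumblebee incl. a 4-species cryptic complex,
64 solitary) plus 8 kleptoparasites. Each species receives a home site
and occupies site j with probability `p0 · exp(−D(home, j)/λ) ·
quality(j)`, Bernoulli-thinned, with `D` the least-cost-path length along
seminatural edges (corridor truth) or Euclidean distance (euclidean
truth), λ = 5 km for solitary bees versus 12 km for bumblebees (smaller
bees disperse less), p0 = 0.85, and site quality a logistic function of
realized plant richness. Occupied cells carry 1 + Poisson(1) individuals.

Default parameter choices, made once: the patch-field smoothing radius
(40 cells) is set so that least-cost corridors detour substantially around
cropland — mean LCP/geographic length ratios near 1.5, the regime reported
for real intensively managed landscapes — because with much smaller
patches LCP length degenerates into a near-copy of geographic distance
and the two distance hypotheses cease to be distinguishable. Site quality
deliberately depends on plant richness but *not* directly on local edge
density: coupling quality to the conductance surface would smuggle
corridor information into every similarity regardless of truth mode and
destroy the generator's ability to separate corridor-following from
Euclidean dispersal (its main purpose). The richness–LLS association
still emerges under corridor truth, through connectivity itself.

What the generator does *not* emulate: observation effort and phenology
(single Bernoulli thinning, no sampling rounds), climate or soil
gradients, species' abundance structure beyond a token count draw, and
landscape change over time. Passing tests therefore demonstrate that the
pipeline recovers known structure from data of this idealized form — not
that field data meet these assumptions.

## Problem sizes and determinism

The test suite runs scaled-down problems chosen as the smallest sizes at
which each property is informative: 3 × 3/4 × 4 grids for exact
path-enumeration oracles, 300–500-cell rasters for placement and decay
properties, n = 300 pair tables for slope recovery, and 50 default
scenarios for the model-selection power/specificity checks. All
randomness flows from explicit seeds; identical seeds give bit-identical
scenario bundles, corridor paths, and reports.

## Known limitations

* Corridor costs are isotropic and slope-free; circuit-theoretic
  (multi-path) connectivity is out of scope.
* The conductance floor means "impossible" movement is merely very
  expensive; on rasters with vast empty regions, reported LCP lengths
  across them are geometric artefacts of the floor.
* Similarity-based connectivity inherits the biases of small samples:
  undersampled sites inflate dissimilarity; the dummy-species device
  mitigates but does not remove this.
* The Student-t family can sit on the df → ∞ boundary for effectively
  Gaussian data; the fit is then flagged rather than failed, and the
  Gaussian family is preferred by the `auto` probe.
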