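# beecorridors

Quantifying the dual role of seminatural **linear landscape structures**
(LLS) — forest edges, grassland margins, verges around sparsely vegetated
ground — as *habitat* and as *dispersal corridors* for wild bee communities
in intensively managed landscapes.

Wild bees are central-place foragers with home ranges mostly under a
kilometre; in cropland-dominated landscapes, the narrow seminatural edges
between land-cover patches concentrate the flowers and nesting substrate
they depend on. `beecorridors` implements the full analysis chain needed to
test, from a categorical land-cover raster and site-level occurrence data,
whether (i) bee species richness increases with the length of seminatural
LLS around a site, and (ii) community similarity between sites is better
explained by least-cost dispersal routes tracking those edges than by
straight-line distance.

## What it computes

**Edge maps.** Patches of forest (land-cover classes 2/3), low woody
vegetation (5), permanent herbaceous grassland (6) and sparsely vegetated
ground (9) are polygonized per class group and their boundary faces traced
as line segments (raster-border and nodata faces excluded; faces shared by
two groups counted once). Per site and radius r ∈ {250, …, 1500} m the
package reports LLS length and grassland cover.

**Richness models.** Poisson GLMs (log link)

    richness ~ log(LLS_r + 1) + plant_richness + log(grassland_r + 1e-4)
               + country + x + y

fitted per radius and LLS type (all seminatural / forest only / nonforest),
compared by AICc = AIC + 2k(k+1)/(n−k−1), with Moran's I (inverse-distance,
row-normalized weights) on Pearson residuals, a Pearson dispersion ratio,
and drop-one likelihood-ratio tests of the LLS term.

**Corridors.** Edge rasters (10 m) are aggregated to 100-m proportion grids
x ∈ [0,1]; an 8-neighbour graph with conductance mean(x_i, x_j)/d_ij and
edge cost 1/conductance yields least-cost paths (Dijkstra, deterministic
tie-breaking). Per within-country site pair the package reports geographic
distance, LCP length, and the accumulated cost Σ(1−x) along the path.

**Distance decay.** Binary Bray–Curtis similarity 2J/(A+B) (with a dummy
species for the sparse solitary-bee subsets) feeds crossed-random-intercept
mixed models

    similarity_ij ~ distance_ij + plantSR_i × plantSR_j + plant_sim_ij
                    + (1|site_i) + (1|site_j)

under Gaussian or Student-t responses, with a 10–105 km threshold
sensitivity analysis (linear vs quadratic distance by ΔAICc) and an AICc
comparison of the candidate distance measures against a null model.

**Synthetic scenarios.** A seeded generator produces a complete toy study —
patchy landscape raster, ≥1 km-separated sites in two countries, plants,
and bee communities whose occupancy decays with corridor (or Euclidean)
distance, faster for solitary bees than bumblebees — so everything above
runs end-to-end with no external data.

## Worked example

```r
library(beecorridors)
bundle <- generate_scenario(scenario_config(seed = 42))
report <- run_pipeline(bundle)
print(report)
```

```
== Habitat-connectivity run report ==
Edges: all seminatural 2835.1 km, forest 696.7 km, nonforest 2138.4 km
Richness models (AICc by radius):
  radius   all forest nonforest
1    250 217.5  218.3     219.8
2    500 217.5  218.4     217.5
3    750 217.7  218.2     217.6
4   1000 216.2  218.7     217.5
5   1250 215.5  218.4     216.6
6   1500 215.8  215.6     217.1
  all: best radius 1250 m (AICc 215.5), beta_LLS 0.734, LRT 4.14 (p 0.042), Moran p 0.779, dispersion 0.48
  forest: best radius 1500 m (AICc 215.6), beta_LLS 0.421, LRT 4.17 (p 0.041), Moran p 0.494, dispersion 0.49
  nonforest: best radius 1250 m (AICc 216.6), beta_LLS 0.548, LRT 3.05 (p 0.081), Moran p 0.582, dispersion 0.50
Corridors: 380 within-country pairs; LCP/geo ratio 1.49 (lls), 2.15 (forest)
  max distance east: NA km
  max distance west: 105 km
Distance-decay model selection (gaussian family):
  sim_all / east: best = lcp_length_lls
  sim_all / west: best = lcp_cost_lls
  sim_solitary / east: best = lcp_length_lls
  sim_solitary / west: best = lcp_cost_lls
```

Reading the output: richness models favour the larger radii and a positive
LLS coefficient on the log-link scale (`beta_LLS`), i.e. sites with more
edge habitat in foraging range host more bee species; residuals show no
spatial autocorrelation (Moran p) and no overdispersion. Corridors along
seminatural edges are on average ~1.5× longer than straight lines, and for
this corridor-structured scenario every country × response comparison ranks
a least-cost-path model above plain geographic distance. An `NA` maximum
distance means no threshold qualified in that country's sensitivity
analysis, in which case all pairs are retained.

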