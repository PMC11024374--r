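# parkequity

Urban park green space (UPGS) is a health resource, and cities distribute
it unevenly: dense old cores often hold the most people and the fewest
parks, while affluent newer districts sit next to the large ones.
`parkequity` is an R package for quantifying that unfairness and planning
around it. It is aimed at urban-planning and public-health analysts who
have (or can simulate) parks with entrances, a walking network, residence
points with households and housing prices, and block populations.

The pipeline has four scientific stages:

1. **Park quality.** Each park's supply combines its area $S$, its
   hard-surface recreational capacity $\mathrm{FCs}$, and an
   ecological-service composite $\mathrm{ESV}$ built from nine
   landscape-pattern indices (MESH, SPLIT, AI, AREA_AM, SHAPE_MN,
   DIVISION, PD, LPI, LSI) of its green land cover — standardized with
   direction and collapsed by PCA. Weights come from an AHP judgment
   matrix with a consistency test (shipped defaults 0.7236 / 0.1931 /
   0.0833).

2. **Accessibility.** A quality-weighted Gaussian two-step floating
   catchment area (G2SFCA) model on network walking distances:

   $$R_j = \frac{w_1 S_j + w_2 \mathrm{FCs}_j + w_3 \mathrm{ESV}_j}
   {\sum_{k: d_{kj} \le d_0} G(d_{kj}, d_0) P_k}, \qquad
   A_i = \sum_{j: d_{ij} \le d_0} G(d_{ij}, d_0) R_j,$$

   with the normalized Gaussian kernel $G$ vanishing at the class-specific
   catchment radius (community 500 m, regional 1000 m, citywide 2000 m,
   comprehensive 3000 m). Whenever every park has demand,
   $\sum_i P_i A_i = \sum_j C_j$ exactly — supplied capacity is conserved.

3. **Equity coupling.** Bivariate local Moran's I between accessibility
   and housing price under row-standardized KNN weights, with conditional
   permutation inference, classifies residences into H-H, H-L, L-H, L-L
   and not-significant. L-L communities are doubly deprived.

4. **Planning.** Explicit blind zones (no entrance within 3000 m) and
   implicit ones (covered but bottom-class service) are identified; the
   optimization targets are low-accessibility ∪ significant L-L
   residences; a K-means curve picks the number of new parks (knee of the
   average farthest member distance, overridable); particle swarm
   optimization minimizes population-weighted distance to the nearest new
   site; sites snap to candidate parcels whose areas fix park classes; and
   the whole analysis re-runs to report before/after changes.

A reproducible synthetic-city generator (dense under-parked core, sparse
fringe, spatially autocorrelated prices, multi-entrance parks with
fragmentation-controlled land cover) drives all examples and tests, so
the package is fully verifiable without proprietary map data. User data
comes in through plain formats: GeoJSON, GraphML, CSV, Esri ASCII grids.

## Worked example

```r
library(parkequity)

cfg <- reference_scenario(seed = 1)
res <- run_pipeline(cfg, out_dir = "parkequity_out", k_new = 8)

res$access
#> Accessibility table: 800 residences
#>   A_500            mean  0.0001225  zero count 748
#>   A_1000           mean   0.000143  zero count 579
#>   A_2000           mean  0.0001445  zero count 124
#>   A_3000           mean  0.0001432  zero count 14
#>   A_comprehensive  mean  0.0001312  zero count 396
#>   lowest-class upper bound: 0.000008

res$lisa
#> Bivariate LISA: n = 800, global I = 0.1932
#>   categories (alpha = 0.05, 999 permutations): HH=81, HL=35, LH=95,
#>   LL=147, NS=442

res$evaluation
#> Plan evaluation: 8 new park(s)
#>   mean accessibility change per radius:
#>     A_500              +7.6e-05 (zero count -58)
#>     A_1000            +8.09e-05 (zero count -187)
#>     A_2000            +7.87e-05 (zero count -85)
#>     A_3000            +7.98e-05 (zero count -4)
#>     A_comprehensive   +7.59e-05 (zero count -100)
#>   LL communities: 147 -> 134; blind (explicit/implicit): 14/388 -> 10/290
```

Reading this: at a 500 m walk, 748 of 800 residences can reach no park at
all; widening the radius to 3000 m leaves only 14 excluded — the classic
signature of a city whose small parks cannot blanket a dense core. The
positive global Moran coupling (0.19) says wealthier neighbourhoods
enjoy systematically better park access. The eight planned parks raise
mean comprehensive accessibility, rescue 100 zero-access residences, and
shrink the doubly deprived L-L set from 147 to 134 communities.

Every stage is also callable on its own (`generate_city()`,
`park_quality()`, `access_table()`, `bivariate_moran()`,
`identify_blind_zones()`, `pso_site_selection()`, `evaluate_plan()`, ...)
and writes/reads plain-text artifacts; `inst/scripts/parkequity.R` is a
thin command-line wrapper over `run_pipeline()`.

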