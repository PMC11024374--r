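---
title: "Park accessibility, equity coupling and siting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Park accessibility, equity coupling and siting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkequity)
```

`parkequity` analyses how fairly urban park green space (UPGS) is
distributed over a city's residents, and where new parks should go. This
vignette explains the models, the parameters that matter, what the
synthetic-city generator does and does not emulate, and the numerical and
design choices behind the implementation.

## The accessibility model

Accessibility uses a quality-weighted Gaussian two-step floating catchment
area (G2SFCA) model. Each park $j$ offers a composite supply

$$C_j = w_1 S_j + w_2\,\mathrm{FCs}_j + w_3\,\mathrm{ESV}_j,$$

where $S_j$ is the park area (hm²), $\mathrm{FCs}_j$ its hard-surface
(paved) area (hm², a proxy for recreational facility capacity) and
$\mathrm{ESV}_j$ an ecological-service composite measuring how
unfragmented its green cover is. The shipped weights
$(w_1, w_2, w_3) = (0.7236,\ 0.1931,\ 0.0833)$ come from an
analytic-hierarchy-process (AHP) pairwise comparison and can be
regenerated from any user judgment matrix with `ahp_weights()`, which also
reports the consistency ratio (pass below 0.1). Since ESV can be negative
for very fragmented parks, a negative composite is floored at zero with a
warning: negative supply has no physical meaning.

**Step 1** computes each park's supply-demand ratio over the population
inside its walking catchment $d_0$:

$$R_j = \frac{C_j}{\sum_{k:\,d_{kj}\le d_0} G(d_{kj}, d_0)\,P_k},
\qquad
G(d, d_0) = \frac{e^{-\frac12 (d/d_0)^2} - e^{-\frac12}}
                 {1 - e^{-\frac12}}\ (d \le d_0),\ \ 0\ (d \ge d_0),$$

with $P_k$ the residence population (households × block mean household
size) and $d_{kj}$ the network walking distance. **Step 2** sums the
ratios back over parks reachable from each residence:
$A_i = \sum_{j:\,d_{ij}\le d_0} G(d_{ij}, d_0) R_j$.

Catchment radii are class-specific: community parks (< 2 hm²) serve
500 m, regional (2-5 hm²) 1000 m, citywide (5-25 hm²) 2000 m and
comprehensive (≥ 25 hm²) 3000 m. A `uniform` mode scans a single radius
for sensitivity analysis. Parks with multiple entrances are reached
through the nearest entrance; the park — not the entrance — is the supply
unit, otherwise a park with four gates would quadruple its capacity and
break the conservation law below.

**Conservation.** When every park has positive weighted demand,
exchanging the two sums gives $\sum_i P_i A_i = \sum_j C_j$: the model
redistributes exactly the supplied capacity. This is the pipeline's
strongest internal check and holds to $10^{-9}$ in the tests. A corollary
worth knowing: the *population-weighted* mean accessibility is constant in
the walking radius whenever all parks have demand, so the unweighted mean
can dip slightly as radii grow; what is guaranteed — and tested — is that
each $A_i$ is non-decreasing in $d_0$ at fixed ratios and that
zero-accessibility counts never increase.

**Units.** Supply enters in hm². Only the scale of $A_i$ changes under a
different unit convention; orderings, classes and all equity conclusions
are invariant.

## Park quality: landscape indices, ESV, FCs

Each park's green cover is a binary raster (1 m cells by default). Nine
class-level landscape-pattern indices are computed on its 4-connected
green patches: MESH, SPLIT and AI (patch spatial arrangement), AREA_AM,
SHAPE_MN and DIVISION (patch shape), PD, LPI and LSI (patch area and
density). The formula sheet is in `?compute_patch_indices`; closed forms
anchor the implementation (a single full patch gives LPI = 100,
DIVISION = 0, SPLIT = 1, MESH = landscape area, AI = 100; a checkerboard
gives AI = 0, and a single green cell — where no like adjacency is
possible — is defined as AI = 0 with a warning). 4-connectivity is the
deliberate, configurable default: it is the conservative choice for
fragmentation (8-connectivity merges diagonal neighbours and can only
lower fragmentation).

AI, LPI and MESH increase with green-structure quality; the other six
decrease. Each index is min-max standardized with that direction (negative
indices are inverted), so 1 always means "least fragmented"; constant
columns map to 0.5 with a warning. The standardized matrix is collapsed by
a correlation-matrix PCA: components with eigenvalue above 1 are retained
(the leading component always is), each is oriented so its loading sum is
positive ("good" points up — PCA signs are otherwise arbitrary),
scores are weighted by each component's share of the retained variance,
and the weighted score is rescaled linearly to mean 50, SD 25 across
parks. Scores can therefore be negative for strongly fragmented parks.
The rescale is an affine convention: any downstream use is invariant to
it up to the AHP weight given to ESV.

## Equity coupling: bivariate LISA

Social equity is read from the spatial coupling between accessibility
($x$) and housing price ($y$, the socioeconomic proxy). With
population-standardized scores, the local bivariate Moran statistic is
$I_i = z_x(i) \sum_j w_{ij} z_y(j)$ and the global statistic is its mean
(exact under row-standardized weights). Weights are k-nearest-neighbour
(k = 8, row-standardized): residences are points, so contiguity is
undefined, and KNN with $k=8$ is the common default for point supports.

Significance uses conditional permutation: $z_x(i)$ stays fixed while the
neighbour values of $z_y$ are re-drawn from the other $n-1$ units, 999
draws by default, two-sided pseudo p-value
$(\#\{|I^{perm}|\ge|I^{obs}|\}+1)/(n_{perm}+1)$. The permuted neighbour
sets are sampled with replacement — a Monte Carlo approximation whose
error is $O(k/n)$; the null calibration test (white-noise $x,y$, $n=500$:
significant fraction $0.05 \pm 0.02$ at $\alpha = 0.05$) confirms it is
immaterial. Significant units are typed by the signs of $z_x(i)$ and the
*spatial lag* of $z_y$ (the standard bivariate LISA convention): H-H,
H-L, L-H, L-L; all others are not significant. L-L units — low
accessibility amid low-priced neighbourhoods — are the double-deprivation
communities the planning stage prioritizes.

## Blind zones, targets, and siting

A residence is an **explicit blind zone** if no park entrance is within
3000 m of network walking. It is an **implicit blind zone** if it is
covered (an entrance within 3000 m) yet receives bottom-tier service:
comprehensive accessibility of zero, or in the lowest positive class of
the geometric-interval classification. "Covered" is read as the 3000 m
entrance criterion rather than each park's own $d_0$; this keeps
explicit/implicit a clean partition of the underserved and matches the
idea that the park network nominally reaches these residents but cannot
serve them.

The geometric-interval classification puts zero scores in their own class
and splits positive scores into $K$ multiplicative intervals
$b_m = a\,(M/a)^{m/K}$ between the smallest and largest positive score —
a documented, reproducible stand-in for the proprietary GIS-vendor
algorithm.

**Optimization targets** are the union of low-accessibility residences
(zero or lowest positive class — the low band includes zero) and
significant L-L residences. The number of new parks comes from a K-means
curve: for each $k$, the average over clusters of the farthest member
distance in a min-max standardized feature space of (comprehensive
accessibility, LISA-category match score with HH = 1, HL = 0.75,
NS = 0.5, LH = 0.25, LL = 0); the knee is the largest positive second
difference, and a planning override (`k_override` / `k_new`) is
first-class because cluster counts chosen from planning context routinely
beat the knee.

**Siting** is a particle swarm (PSO) minimizing
$f(s) = \sum_t P_t \min_s \|t - s\|$ — the population-weighted distance
from each target to its nearest new site — with standard
constriction-style parameters (inertia 0.729, cognitive = social =
1.494), velocity clamped to 20% of the bounds span, and a fixed seed for
exact reproducibility. The best objective is non-increasing by
construction, and on $k=1$ problems the swarm lands within 1% of a 1 m
exhaustive grid search. Land use enters afterwards: each continuous site
snaps to the nearest unused candidate parcel (next-nearest on conflict),
and the parcel's area fixes the new park's class and radius through the
same class cutoffs. This deterministic snap replaces the study-style
manual refinement against a land-use plan.

**Evaluation** appends the planned parks (entrances snapped into the road
network; ESV from per-class defaults, FCs from a default hard fraction of
0.2) and re-runs accessibility and equity with identical seeds. Existing
parks keep their measured quality, so stripping the new parks reproduces
the before state exactly — tested to $10^{-9}$.

## The synthetic-city generator

No real scraped park/price/population data ship with the package, so a
generator produces cities with the statistical structure the analysis
assumes, on abstract planar meters (the analysis needs only metric
distances, so no CRS):

* a jittered grid road network; every entrance becomes a road vertex
  joined to its nearest grid node, so walking distances are plain
  shortest paths;
* residences from a **three-level density**: a dense core (the central
  quarter of the area, default 4× the built-up periphery), a built-up
  ring, and a sparse exurban fringe (default 5% relative density —
  roughly the ~1% share of settlements a large inland city has beyond
  3000 m of any park, kept slightly higher so fringe behaviour remains
  testable at n = 800). A flat two-level city is the special case
  `fringe_density_ratio = 1`, under which the realized core/periphery
  density ratio matches `core_density_ratio` within ±25%;
* housing prices rising away from the cheap, dense old core (negative
  default gradient), plateauing at the outskirts, plus spatially
  correlated noise built from moving-average-smoothed white noise — the
  autocorrelation is what matters, not the exact covariance family;
* parks of the four size classes confined to a development ring
  (`park_ring_max`) and thinned in the core (`core_park_prob` = 0.15):
  parks follow development, the old core is under-parked, and the far
  fringe has none — which is precisely what produces central implicit
  blind zones and fringe explicit blind zones;
* per-park binary land-cover rasters with an exact number of 4-connected
  green patches, grown by randomized frontier expansion inside separated
  tiles; 1 m cells by default;
* candidate parcels anywhere in the extent (plans need parcels in the
  core).

What the generator does **not** emulate: clustered estate microstructure
(residences are independent points given the density), park shapes beyond
rectangles, road hierarchies and barriers, or any behavioural demand
model. Passing tests therefore show the *pipeline* is correct and that
its qualitative conclusions follow from the assumed structure — not that
any particular real city has these properties.

The **reference scenario** (`reference_scenario(seed)`) is a 10 × 10 km
city, 800 residences, 14 parks (6/4/3/1 across the four classes). The
end-to-end checks run it over five seeds with a paper-intensity override
of 8 new parks (~1 per 100 residences); under those conditions implicit
blind residences concentrate ≥ 80% in the core, the plan strictly raises
mean comprehensive accessibility, and zero-accessibility and L-L counts
never increase.

## Numerical choices and degenerate inputs

* Distances: points snap to the nearest road vertex with the Euclidean
  connector added; points beyond 500 m (configurable) are excluded with a
  warning. Pairs beyond the 3000 m cutoff are not stored.
* `classify_geometric` nudges its breaks by one part in $10^{12}$ so a
  value sitting on a break (up to floating-point noise) stays in the
  lower class.
* K-means runs `n_init` seeded starts per $k$; the curve is treated as
  non-increasing within a 2% clustering tolerance (local-optimum jitter).
* Ties in parcel snapping resolve by first index; two sites wanting the
  same parcel resolve sequentially (next-nearest).
* Degenerate inputs error early with the offending field named:
  single-park standardization, fewer than three parks for PCA, constant
  variables in the Moran statistic, k ≥ n for weights, infeasible patch
  counts, parks that cannot be placed in the extent.
* Problem sizes in the shipped tests (chosen to exercise every code path
  at comfortable speed): 20 × 20 oracle rasters, n = 200-500 Moran
  checks with 999 permutations, 150-residence unit cities, five
  800-residence reference runs.

## Known limitations

Walking is the only travel mode; slope and crossings are ignored. ESV is
a fragmentation composite, not a full ecosystem-service valuation; FCs is
a hard-surface proxy. The AHP weights ship as constants because the
original pairwise judgments are not public — regenerate them from your
own matrix for serious use. The geometric-interval classes and the PCA
composite are documented conventions among several defensible ones, and
conclusions that depend on class *boundaries* (rather than orderings)
should be checked for sensitivity.
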