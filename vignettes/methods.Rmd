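---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and procedures, the assumptions behind them, the tunable
parameters and their defaults, what the synthetic world does and does not
emulate, and the choices made where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## Geometry and grids

All coordinates are lon/lat WGS84. Rasters are north-up matrices with row
1 at the top; cell (r, c), 1-based, has center
`(origin_lon + (c − 0.5)·s, origin_lat − (r − 0.5)·s)` for cell size `s`
in decimal degrees. The working resolution of the methodology is 2.5 arc
minutes (≈ 4.63 km, conventionally "about 5 km", at the equator), but
every operation is resolution-generic and the tests run on 0.5° grids.
Distances use the haversine formula on a sphere of mean radius 6371 km; no
geodesy model beyond the sphere is attempted. Cell areas use the spherical
approximation `(s · 111.195 km)² · cos(latitude)`, which is adequate at
these resolutions and far from the poles.

Point-in-polygon membership is even-odd ray casting with holes. **A point
exactly on any ring edge counts as inside.** Some boundary convention has
to be fixed for the cell-center rasterization rule to be deterministic;
"on the edge is in" is the simplest one, and the tests pin it.

Raster interchange is the plain-text ESRI ASCII grid and polygon
interchange is GeoJSON. The original workflow used GeoTIFF and shapefiles;
neither format has an offline-capable reader in this package's dependency
budget, and the formats are interchange details, not method.

## Species selection

Selection from the WEP-style tables retains a species iff it has at least
one use outside the excluded categories and is not strictly cultivated.
The excluded-category default — `weed`, `poisonous`, `ornamental`,
`potential_genetic_resource_only` — encodes the methodology's filter; the
underlying database's internal codes are not public, so use categories are
treated as an opaque controlled vocabulary and "strictly cultivated" is an
explicit boolean input column rather than a derived judgment. Name
standardization is table-driven (precomputed raw → accepted name mapping);
synonym collisions merge entries with unioned use and country sets.

## Occurrence scrubbing

A record is kept iff (it has no coordinates, or its cell is land) and its
country is in the species' native range and (its year is absent or
≥ 1950). Decisions behind the contract:

* The water test uses the land-mask raster at cell resolution, not vector
  coastlines — deterministic and matches the published mask artifact.
* The record's country is its ISO3 field when present, else the country
  polygon containing the point; a record whose country cannot be
  determined fails the native-range test (conservative).
* Records without coordinates are *kept*: they still count for the
  sampling score, but cannot enter modeling.
* A record violating several rules gets exactly one reason, in the fixed
  precedence `off-grid > water > non-native > too-old`, so rejection
  reports are reproducible.
* The N/I native-status column is recorded but not filtered on; the
  native-range test is the country test.

## The predictor stack

26 layers in a fixed order: bioclim 01–19, solar radiation, wind speed,
water vapor pressure, altitude, slope, aspect-NS, aspect-EW. Slope and
aspect derive from altitude with Horn's 8-neighbor gradients; the east-west
cell size is converted to meters with a cos(latitude) factor per row.
Aspect, a circular variable, is decomposed as (cos θ, sin θ) of the
downslope compass direction θ — the standard way to feed a circular
variable to a linear model; the original data name the two components
without stating the transform. Flat cells map to (0, 0) rather than
nodata so they remain modelable; wherever slope > 0 the two components
satisfy ns² + ew² = 1.

## Distribution modeling

The presence/background model is the penalized-logistic equivalent of the
MaxEnt family: linear + quadratic features of all 26 predictors (52
features), standardized by background means/sds, fit with an L1 penalty by
glmnet. Feature classes stop at quadratic: enough to express a Gaussian
response on any predictor axis, which is the niche family the synthetic
world plants; hinge/product/threshold features are out of scope.

Parameters (all exposed via `sdm_config()`):

| parameter | default | why |
|---|---|---|
| `min_presences` | 10 distinct cells | below this a model is not attempted (CA50 only); conventional floor for this methodology |
| `background_n` | 10,000 | capped at the number of eligible land cells; drawn uniformly without replacement, excluding presence cells, seeded |
| `k` | 5 folds | presence partition; background shared across folds |
| pass rule | mean test AUC ≥ 0.7 and sd ≤ 0.15 | "passed all validation metrics" is not enumerated in the source; these defaults are documented, not asserted as the original authors' |
| `reg` | 1 (λ = reg · 0.001) | see below |
| threshold | max(sensitivity + specificity) | conventional for this methodology; ties resolved to the lowest candidate; cells ≥ threshold are presence |
| `ca50_km` | 50 km | the circular-area buffer radius; membership is by cell-center distance, consistent with the cell-center rasterization rule |

The base penalty λ = 0.001 at `reg = 1` was chosen after observing that a
ten-fold stronger penalty could not express sharp quadratic niche
responses at n ≈ 10³ (validation AUC plateaued near 0.89 on arbitrarily
tight planted niches — a model defect, not a data property). 0.001 is a
typical terminal-lambda magnitude for binomial glmnet fits at these sample
sizes and still produces sparse models with a monotone L1 path (doubling
`reg` never grows the active set; pinned by a test). Each fit is
warm-started down a fixed descending lambda sequence ending at the target,
which makes that monotonicity robust.

Pseudo-absences are drawn worldwide from the mask (not restricted to the
native region); the original description is ambiguous and worldwide is the
literal reading. The predicted surface is the logistic probability, which
is already the [0, 1] scale; no min-max stretch is applied — a stretch
would force uninformative models to span [0, 1] and contradict the
expected near-flat no-signal behavior.

Species fall back to CA50 — cells whose center is within 50 km of any
occurrence, intersected with the land mask — when presences are too few or
validation fails. CA50 satisfies `ca50(A ∪ B) = ca50(A) ∨ ca50(B)` and is
tested against a brute-force double loop.

## Rasterization rules

Ecoregions use the *cell center* rule: a cell takes the category of the
polygon containing its center (earliest polygon wins on overlap — the
original tool's tie behavior is undocumented, lowest index is ours).
Protected areas use the *maximum area* rule: a cell takes the category
covering the largest fraction of the cell, fraction 0 is nodata, ties go
to the lowest id. Coverage is the union over a category's polygons,
estimated on an s×s sub-point lattice per cell (default s = 16; the
acceptance oracle uses 32). Sub-point counting was chosen over exact
polygon clipping because it is deterministic, independently checkable by
a naive oracle, and accurate at the method's resolution; doubling s
changes under 1% of cells on random fixtures (tested). The WDPA filter
keeps status ∈ {designated, inscribed, established} (case-insensitive) and
domain ∈ {terrestrial, coastal}; the binary protected-area raster maps
assigned → 1 and everything else → 0 with no nodata, per the layer's 0/1
contract. Both rules coincide when polygon edges lie on cell edges
(tested), and callers pass one explicit grid — the original workflow's two
template grids are an artifact of its tooling, not of the method.

## Scores

With G = germplasm records, H = reference records, D = distribution
raster, B = CA50 buffer on georeferenced G records, P = protected-area
raster, E = ecoregion raster, and area() the cos-latitude cell-area sum:

* SRS_ex = 100·G/(G+H); GRS_ex = 100·area(B∧D)/area(D);
  ERS_ex = 100·|ecoregions(B∧D)|/|ecoregions(D)|
* SRS_in = 100·(occurrences in P cells)/(georeferenced occurrences);
  GRS_in = 100·area(D∧P)/area(D); ERS_in = 100·|ecoregions(D∧P)|/|ecoregions(D)|
* FCS_ex, FCS_in = unweighted three-component means; FCS_combined = their
  mean; categories < 25 urgent, [25, 50) high, [50, 75) medium, ≥ 75 low.

Every score with an empty denominator is defined as 0, not 100: absent
data must not read as conservation success. D is the validated model
presence when available, else the all-records CA50. SRS_in counts all
georeferenced occurrences (not only G); the original is silent and this is
config-switchable. The 25/50/75 thresholds follow the companion
methodology and are config-exposed.

## Indicator aggregation

A species contributes to every scope (country, M49 sub-region, region,
global) whose member countries intersect its native-country set — full
membership in each, no fractional allocation, and no range-size weighting:
scope values are unweighted species means. Sub-regions must partition
regions; a country classified twice is an error, not a warning.

## The synthetic world

The generator emits every input contract with closed-form ground truth:
a 60×60 grid of 0.5° cells centered on the equator; a land block with a
3-cell ocean margin and a 4×4 inland lake; countries as vertical strips of
the land block; ecoregions as horizontal bands; one protected-area
rectangle sized to the target protected fraction (plus decoy polygons with
non-qualifying WDPA status/domain that the filter must drop); 22 smooth
seeded climate fields plus a deterministic altitude surface; and species
with Gaussian niches on bioclim 01 sampled into G/H records, with planted
water / pre-1950 / non-native violations whose exact counts the scrub step
must recover.

Default sizes (8 species; 15 G + 35 H records each, 3+2+2 planted
violations; 4 countries; 5 ecoregions; protected fraction 0.25; niche
breadth 1.5) were chosen once as a desk-scale caricature of the real
workload — tens of records per species and a minority of records being
germplasm accessions are typical of the real data; the violation counts
are small but nonzero so every rejection path is exercised.

The niche predictor is generated from the same smooth-field family as the
other climate layers but with *fixed* coefficients. An earlier design used
a pure latitudinal gradient; that made the niche axis collinear with
latitude and hence with the altitude-derived layers, and no method could
attribute the niche to the planted variable. Identifiability of the
planted signal is a property of the stated world, not a tuning knob.

What the world does **not** emulate — and what a green test therefore does
not establish: realistic covariance between climate layers (real bioclim
variables are strongly correlated; lasso selection among correlated real
predictors will be less stable than here), real coastline and reserve
geometry, spatial sampling bias in occurrence data, taxonomic noise, and
scale (thousands of species, millions of cells). Green tests establish
correctness of the rules and scores on worlds where their answers are
knowable, and sane statistical behavior of the modeling step — not
ecological realism.

## Numerical choices and degenerate inputs

* Boundary points are inside polygons; cell-boundary points belong to the
  south/east cell (floor indexing).
* `which.max` tie-breaks: thresholding takes the lowest optimal candidate;
  max-area takes the lowest category id.
* Zero-variance predictors over the background are dropped with a warning
  before fitting; an all-degenerate stack is an error.
* A constant probability surface thresholds to all-presence (≥ rule).
* CA50 with zero points, mixed-species record frames, grid mismatches
  between layers, and out-of-range component scores are errors, not
  silent recoveries.
* Seeds: every stochastic step (background draw, fold assignment, world
  generation, occurrence sampling) takes an explicit seed and restores the
  caller's RNG state afterwards; the full pipeline is byte-deterministic
  for a fixed seed (tested by file comparison).

## Known limitations

Beyond the synthetic-world caveats above: no hinge/product/threshold
features and no clipping of models to native-area polygons (scrubbing
already restricts presences); no duplicate-record detection; no
uncertainty intervals on scores; no antimeridian-crossing polygons or
projected coordinate systems; the max-area rule is an estimate (sub-point
lattice), not exact clipping. The validation pass rule and the SRS_in
record basis are documented defaults, not values asserted from the
original workflow.
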