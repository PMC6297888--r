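# plantgap

Conservation gap analysis and indicator pipeline for useful wild plants.

## The problem

Thousands of wild plant species are of direct socioeconomic or cultural
value — crop wild relatives, wild food plants, medicinal and forage
species. How comprehensively are they conserved, both *ex situ* (as
germplasm accessions in genebanks and living repositories) and *in situ*
(inside protected areas)? `plantgap` implements the full analysis pipeline
behind a comprehensiveness-of-conservation indicator for such species, for
conservation scientists and biodiversity-indicator analysts:

1. **Taxa** — parse species/use/country tables in the layout of the
   GRIN-Global World Economic Plants (WEP) extract and select the useful
   wild species (dropping weeds, poisonous plants, ornamentals,
   potential-only genetic resources, and strictly cultivated species).
2. **Occurrences** — classify records as germplasm (G) or reference (H),
   then scrub: drop coordinates in water, records outside the species'
   native range, and reference records collected before 1950 (undated
   records are kept).
3. **Predictors** — assemble the 26-layer eco-geographic stack (19 bioclim
   variables, solar radiation, wind speed, water vapor pressure, altitude,
   plus slope and two aspect components derived from altitude by Horn's
   method).
4. **SDM** — a MaxEnt-style presence/background model: linear + quadratic
   features, L1-penalized logistic regression, pseudo-absences drawn from
   the land mask, 5-fold test-AUC validation, max(sensitivity+specificity)
   thresholding; species with too few presences or failing models fall back
   to **CA50**, the set of land cells within 50 km of any occurrence.
5. **Rasterize** — the two polygon-to-raster rules of the original
   workflow: *cell center* (ecoregions) and *maximum area* (protected
   areas), plus the WDPA status/domain filter (designated, inscribed or
   established; terrestrial or coastal).
6. **Conservation scores** — per species, on each axis sampling (SRS),
   geographic (GRS) and ecological (ERS) representativeness, 0–100:

   | score | ex situ | in situ |
   |---|---|---|
   | SRS | 100·G/(G+H) | % of occurrences in protected cells |
   | GRS | % of distribution area inside the G-record CA50 buffer | % of distribution area protected |
   | ERS | % of the distribution's ecoregions touched by the buffer | % of ecoregions protected |

   FCS_ex and FCS_in are the unweighted means of their three components,
   FCS_combined their mean, with priority categories
   < 25 urgent, 25–50 high, 50–75 medium, ≥ 75 low.
7. **Indicator** — mean FCS values over all species native to each
   country, UN M49 sub-region, region, and globally.
8. **Synthgen** — a deterministic synthetic world (rectangular countries,
   ecoregion bands, protected-area rectangles, smooth climate fields,
   Gaussian-niche species with deliberately dirty records) with complete
   ground truth, so the entire pipeline runs and is verified at desk scale
   with no downloads.

## Worked example

```r
library(plantgap)

world <- generate_world(world_config())        # 60x60 synthetic world, 8 species
res   <- run_pipeline(world, seed = 1)

round(res$scores[1:4, c("srs_ex","grs_ex","ers_ex","fcs_ex",
                        "srs_in","grs_in","ers_in","fcs_in","fcs_combined")], 1)
#>   srs_ex grs_ex ers_ex fcs_ex srs_in grs_in ers_in fcs_in fcs_combined
#> 1   34.9    3.7    100   46.2   32.6   30.8     40   34.5         40.3
#> 2   34.9   38.4    100   57.8   20.9   23.9     40   28.3         43.0
#> 3   34.9    4.5    100   46.5    7.0    3.4     40   16.8         31.6
#> 4   34.9    3.7     80   39.5   25.6   24.0     40   29.9         34.7
```

Reading row 1: 34.9% of the species' records are germplasm accessions
(srs_ex); the 50-km buffer around those accessions covers only 3.7% of its
modeled range (grs_ex) but touches all of the range's ecoregions (ers_ex
100); 30.8% of the range is protected (grs_in). Its combined score 40.3
puts it in the "high priority" category. Aggregated:

```r
res$indicator[res$indicator$level == "global",
              c("scope_id","n_species","mean_fcs_combined")]
#>   scope_id n_species mean_fcs_combined
#> 8   global         8             34.69
```

On this synthetic world the indicator says: averaged over all 8 species,
comprehensiveness of conservation is 34.7 out of 100 — all species in the
high-priority band.

## Layout

- `R/` — grid/polygon primitives, taxa, occurrences, predictors, sdm,
  rasterize, conservation, indicator, synthgen, pipeline
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (`helper-oracles.R`)
- `vignettes/methods.Rmd` — the model, its assumptions, parameter defaults
  and limitations
- `inst/cli/plantgap.R` — command-line entry point (`synthgen`,
  `pipeline`, `taxa`)
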