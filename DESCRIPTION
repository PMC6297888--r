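Package: plantgap
Title: Conservation Gap Analysis and Indicator Pipeline for Useful Wild Plants
Version: 0.1.0
Authors@R: person("Plantgap", "Developers", email = "plantgap@example.org",
    role = c("aut", "cre"))
Description: Tools to compute the comprehensiveness-of-conservation indicator
    for socioeconomically valuable wild plant species. The pipeline runs from
    species/use/country tables and georeferenced occurrence records through
    occurrence scrubbing, a 26-layer eco-geographic predictor stack,
    presence/background species distribution models with a 50-km circular-area
    fallback, polygon rasterization rules for ecoregions and protected areas,
    per-species ex situ and in situ representativeness scores (SRS, GRS, ERS,
    FCS), and aggregation of species scores to country, sub-regional, regional
    and global indicator values. A deterministic synthetic-world generator
    emulates every input so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
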