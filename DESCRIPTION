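Package: divelev
Title: Diversification Rates and Lineage Ages Along Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links genus occurrence records from banded mountain transects
    with a time-calibrated phylogeny to analyse how net diversification
    rates and lineage ages distribute along elevational and thermal
    gradients. Estimates per-genus Magallon-Sanderson stem-age
    diversification rates, aggregates them into per-band means (DivElev,
    AgeElev) with relative elevation and richness, calibrates
    elevation-to-Bioclim climate models per gradient, fits beta
    regressions (logit link, constant precision) and identity-link
    Poisson-variance generalized linear models with likelihood-ratio and
    AICc model comparison, quantifies phylogenetic signal in thermal
    preference with Pagel's lambda, and reconstructs ancestral
    temperature preferences under Brownian motion. A seeded synthetic
    data generator emulates the full data structure (birth-death
    chronogram, trait evolution, thermal-niche band occupancy) so every
    stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    jsonlite
Config/testthat/edition: 3
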