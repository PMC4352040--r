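Package: sensimod
Title: Sensitized RNAi Modifier Screens and TMT Phosphoproteomic Set Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for differential (sensitized) RNAi modifier
    screens and six-plex TMT phosphoproteomics. Converts 384-well plate
    luminescence readings into per-amplicon Z and ZDiff scores against
    in-plate controls, calls Suppressor/Enhancer/Upstream modifier classes,
    averages amplicon scores into per-gene ZDiffFinal values with
    high-confidence calls, estimates screen false-positive and
    false-negative rates, and tests protein-complex over-representation by
    gene-set resampling. A companion phosphoproteomics branch filters
    PSM-level reporter-ion tables (AScore, isolation specificity,
    target-decoy FDR), corrects TMT channel impurities, normalizes and
    replicate-averages intensities per phosphosite, and classifies sites
    into receptor-specific, common and hormone-responsive differential sets
    by fold-change logic, with k-means profile clustering. Ships seeded
    synthetic-data generators with planted ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
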