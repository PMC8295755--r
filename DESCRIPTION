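Package: provdrought
Title: Quantitative Genetics of Tree Drought Response in Provenance Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for estimating quantitative genetic variation in the
    drought response of forest trees growing in common-garden provenance
    trials. Reads increment-core ring-width series (Tucson/rwl or long CSV)
    and monthly station precipitation, interpolates precipitation to trial
    sites by inverse distance weighting, computes the standardized
    precipitation index (SPI) at multiple time scales to identify drought
    years, derives per-tree Lloret resistance and recovery indices from raw
    ring widths, quantifies provenance phenotypic stability by
    Finlay-Wilkinson joint regression and Spearman rank correlation, and
    estimates repeatability (the upper bound of heritability) and
    evolvability (the coefficient of additive genetic variation) from REML
    variance components of tree-level random-intercept models. A seeded
    synthetic-data generator with known provenance, tree and event structure
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    multcomp,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
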