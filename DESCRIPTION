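Package: aiskrige
Title: Probability Co-Kriging Risk Maps for Aquatic Invasive Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to map the risk of aquatic invasive species introductions
    across a lake-rich landscape under imperfect, publicly reported
    surveillance. Builds a boater-traffic contact network from watercraft
    inspection surveys and computes node centralities; assembles
    waterbody-specific covariates (invasion status, stream connectivity via
    shared route identifiers, traffic centrality, inverse distance to major
    roads); fits direct and cross semivariograms under a linear model of
    coregionalization and predicts introduction probabilities by ordinary
    indicator co-kriging on a water-masked grid; classifies waterbodies into
    five quantile risk ranks; and validates predictions by temporal
    (census-to-census) validation and k-fold cross-validation with ROC/AUC
    and sensitivity/specificity summaries. A seeded synthetic-landscape
    generator emulates clustered waterbodies, streams, roads, invasion
    growth between censuses, and an accessibility-biased reporting process
    so the whole pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
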