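Package: sulfidiv
Title: Phenotypic Divergence and Gene Flow Across Sulfide-Spring Fish Population Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying ecological speciation along hydrogen
    sulfide gradients in livebearing fishes. Couples landmark-based geometric
    morphometrics (generalized Procrustes analysis, relative warps) with nested
    multivariate analyses of covariance, canonical divergence vectors for the
    habitat term, Weir-Cockerham F_ST from microsatellite genotypes, and
    (partial) Mantel permutation tests, then integrates per-system divergence
    scores with genetic differentiation and H2S concentration. Includes a
    synthetic-data generator emulating a replicated sulfidic/non-sulfidic
    study design so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
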