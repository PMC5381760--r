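Package: melaniche
Title: Phenotype-Stratified Niche Modelling of Coat-Colour Melanism
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the geographic distribution of a discrete
    coat-colour polymorphism (melanism) across a species range: occurrence
    record validation, deduplication and landscape-change filtering;
    biome-by-phenotype contingency statistics with adjusted residuals; a
    kernel-guided complete-spatial-randomness Monte Carlo test; a from-scratch
    maximum-entropy presence-background niche model with the classic run
    protocol (correlation-based predictor pre-selection, 70/30 bootstrap
    replicates, background AUC, permutation variable importance); niche
    overlap statistics (Schoener's D, Hellinger-based I, relative rank) with a
    reciprocal-resampling equivalency null; and environmental driver
    contrasts including a geographic barrier moisture test. A synthetic
    landscape generator with known niche structure makes the entire pipeline
    testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
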