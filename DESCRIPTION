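Package: ednaflow
Title: Interaction Networks and Temperature Sensitivity from Quantitative eDNA Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies fish-fish interactions from quantitative
    environmental DNA (eDNA) metabarcoding time series. Sequence reads are
    converted to eDNA copy numbers via an internal spike-in standard, directed
    interactions are detected as conditional transfer entropy estimated by
    nearest-neighbour cross mapping on time-delay embeddings with bootstrap
    tests, time-varying interaction strengths are estimated with the multiview
    distance regularized (MDR) S-map, and the temperature dependence of
    interaction strengths is modelled with gamma-family generalized additive
    mixed models. A synthetic multispecies community simulator with analytic
    interaction Jacobians provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
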