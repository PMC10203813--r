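Package: somatomap
Title: Somatotopic Digit-Map Analysis for Active and Passive Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of digit somatotopy in primary
    somatosensory cortex as measured with task fMRI. Generates synthetic
    cortical sheets, digit activity patterns and travelling-wave localiser
    time series; localises digit-specific clusters by lagged reference-model
    correlation with winner-take-all assignment and per-digit FDR control;
    quantifies cross-task spatial correspondence with a minimum-normalised
    Dice coefficient; scores somatotopic ordering with a weighted
    digit-preference index and circular correlation; analyses within-cluster
    neighbourhood selectivity with repeated-measures inference; computes
    cross-validated Mahalanobis (crossnobis) representational dissimilarity
    matrices with residual-based prewhitening, typicality and MDS summaries;
    and probes gain-modulation versus digit-enslavement accounts of task
    differences with a five-unit laterally connected cortical model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
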