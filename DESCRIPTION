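Package: NemaScreen
Title: Worm-Based Olfactory Screening: Calcium-Imaging Trace Extraction,
    Neuronal Activation Index and Cohort Discrimination
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Caenorhabditis elegans olfactory
    screening of biofluid samples. Extracts per-neuron normalized
    fluorescence traces (dF/F0) from wide-field calcium-imaging stacks
    with constrained maximum-intensity tracking and frame-difference
    motion rejection, calls odor-removal activation events with a
    3-sigma rule, computes the Neuronal Activation Index (NAI) and the
    Chemotaxis Index (CI) with binomial dispersion, and performs
    cohort-level discrimination (sensitivity/specificity/accuracy, ROC
    curves, two-variable PCA). A synthetic-data module generates image
    stacks, cohorts and plate counts with ground-truth sidecars so every
    stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
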