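Package: dynfc
Title: Dynamic Functional Connectivity Metastates and Network-Based Statistics
Version: 0.1.0
Authors@R:
    person("dynfc", "maintainers", email = "dynfc@example.org", role = c("aut", "cre"))
Description: Time-resolved functional connectivity analysis for task fMRI
    region-of-interest time series. Implements multiplication of temporal
    derivatives (MTD) coupling with non-overlapping windows, multilayer
    (time-linked) modularity maximisation with partition dynamics metrics
    (flexibility, allegiance, recruitment/integration), cartographic-profile
    labelling of windows as integrated or segregated metastates via k-means,
    per-participant integrated connectivity networks, and Network Based
    Statistics (edge-wise GLM, supra-threshold components, permutation
    family-wise-error inference with Freedman-Lane covariate handling).
    Includes a synthetic multi-run BOLD cohort generator with known
    state-switching community structure and a planted sub-network to
    symptom-change association, motion and signal-dropout quality control,
    and an end-to-end seeded pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
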