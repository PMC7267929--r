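Package: cobemcd
Title: Common Orthogonal Basis Extraction and Maximal-Dissimilarity
    Subtyping for Multi-Run Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts the spatial component shared by all resting-state
    fMRI runs of a subject via common orthogonal basis extraction (COBE),
    builds the subject-by-subject correlation matrix of these common
    components, selects a maximal-dissimilarity (MCD) subgroup by
    randomized maximal-set growth with restarts, and characterizes the
    subgroup against the remaining similar (CS) subjects through
    network-averaged weight contrasts and a Bonferroni-corrected
    behavioral battery, including a sex-matched resampling control.
    Ships a synthetic-data generator that plants a known common
    component, a dissimilar subgroup with reduced default-mode weights,
    behavioral group effects and sex imbalance, so the whole pipeline is
    testable without access to restricted imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
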