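Package: msdimensions
Title: Data-Driven Dimensions of Multiple Sclerosis Neuropathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers independent dimensions of multiple sclerosis
    neuropathology from donor-level autopsy data. Implements the full
    pipeline: derivation of donor-level lesion features, centered log-ratio
    transformation of compositional blocks with multiplicative zero
    replacement, regularized iterative factor-analysis-of-mixed-data (FAMD)
    imputation with cross-validated selection of the number of components,
    FAMD itself, iterative removal of highly contributing outlier donors via
    medcouple-adjusted boxplot fences, and rank-based validation of the
    resulting dimensions against clinical and neuropathological covariates
    with family-wise Benjamini-Hochberg false-discovery-rate control. A
    synthetic-cohort generator with known latent structure makes every stage
    testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
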