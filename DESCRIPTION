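Package: taxera
Title: Compositional Microbiome Analysis of Hospital-Era Cohort Differences
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying gut-microbiota taxa
    that discriminate two clinical eras in longitudinally sampled hospital
    cohorts. Provides centered log-ratio (clr) transforms and Aitchison
    distances for genus-level count tables, PERMANOVA and beta-dispersion
    permutation tests, sparse partial least squares discriminant analysis
    (sPLS-DA) with leave-one-out selection stability and AUROC, a
    time-decaying antibiotic-exposure score over daily administration
    records, covariate-adjusted per-taxon linear regression with
    Benjamini-Hochberg correction and volcano selection, and a
    leave-one-patient-out robustness screen. A synthetic cohort generator
    with planted effect sizes makes every stage testable without external
    sequence data.
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
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
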