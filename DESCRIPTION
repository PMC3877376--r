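Package: melprs
Title: Polygenic Risk Score Modelling, Meta-Analysis and Risk
    Reclassification for Melanoma Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds weighted polygenic risk scores (PRS) from small SNP
    panels and carries them through a complete case-control analysis:
    per-SNP additive logistic models, covariate-adjusted PRS association
    (continuous, tertile, allele-count band and top-percentile contrasts),
    DerSimonian-Laird random-effects meta-analysis with Cochran Q and
    I-squared heterogeneity statistics, ROC/AUC model comparison with
    paired DeLong contrasts, and categorical net reclassification
    improvement (NRI) and integrated discrimination improvement (IDI).
    Includes a synthetic cohort generator that simulates Hardy-Weinberg
    genotypes, a logistic disease model and study-specific covariate
    schemes so the whole pipeline is testable without access to
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    pROC,
    vcfR,
    optparse
Config/testthat/edition: 3
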