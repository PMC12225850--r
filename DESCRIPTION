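Package: ldlstrat
Title: Stratified TG/VLDL-C Ratio Estimation of LDL Cholesterol
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of low-density lipoprotein cholesterol (LDL-C) from
    standard fasting lipid panels using the Friedewald formula and
    Martin-Hopkins-style stratified lookup of the triglyceride to VLDL
    cholesterol ratio. Derives strata-specific median ratios with
    distribution-free confidence intervals and concordance-optimal ratios by
    grid search against NCEP-ATP III guideline categories, and evaluates
    estimators by category concordance (Clopper-Pearson exact intervals,
    exact McNemar tests), treatment-category reclassification, Bland-Altman
    agreement, and fit metrics. Includes a synthetic lipid-cohort generator
    with lognormal marginals and a Gaussian copula for fully reproducible
    end-to-end testing without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
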