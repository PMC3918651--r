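Package: admixcor
Title: Individual Admixture Proportions and Cardio-Metabolic Association
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of per-individual two-way
    admixture proportions from panels of ancestry-informative markers
    under a Hardy-Weinberg genotype model, together with the downstream
    epidemiological analysis of an admixed cohort: derivation of
    cardio-metabolic variables (body-mass index, HOMA-IR, obesity,
    insulin-resistance and diabetes classification), age- and
    sex-adjusted correlations, likelihood-ratio tests of effect
    modification, stratified forward-stepwise linear regression, and
    penalized cubic-regression-spline tests of linearity.  A calibrated
    synthetic-cohort generator makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
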