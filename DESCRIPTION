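Package: vaproj
Title: Facility-Based Projection of Population Causes of Neonatal and Child Death
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating population-level cause-specific mortality
    fractions (CSMFs) of neonatal (0-27 days) and child (1-59 months) deaths
    from verbal-autopsy records with a complex survey design. Provides
    survey-weighted CSMF estimation, the CSMF-accuracy statistic with
    percentile bootstrap confidence intervals formed by resampling primary
    sampling units, per-cause community-versus-facility comparisons via a
    Rao-Scott corrected chi-square with a Fisher exact fallback, five schemes
    for projecting the population cause distribution from facility deaths
    (direct substitution, multinomial logistic regression, and random forests
    with varying covariate sets), a facility-share sensitivity sweep, and a
    synthetic study generator with known generative truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
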