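Package: devomatrix
Title: Developmental, Genetic and Phenotypic Covariance Matrices from
    Bilateral Landmark Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying developmental variability in bilateral
    landmark shape data and testing its alignment with standing genetic
    variation and environmental shape change. Reads and simulates replicated
    two-sided landmark configurations, performs generalized Procrustes
    superimposition with reflection of one side, decomposes shape variance
    with a bilateral Procrustes ANOVA (directional and fluctuating
    asymmetry, measurement error), estimates developmental (D), broad-sense
    genetic (G) and phenotypic (P) covariance matrices by moment and REML
    variance-component estimators with reduced-rank factor-analytic models
    and AIC rank selection, and compares matrices via Krzanowski
    common-subspace analysis, random skewers, leading-eigenvector
    correlations and the e-beta statistic, with REML-MVN resampling and
    bias-corrected accelerated (BCa) confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
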