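Package: metfa
Title: Factor-Analytic Mixed Models and Stability Analysis for
    Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of unbalanced multi-environment plant breeding
    trials with restricted maximum likelihood (REML) mixed models.
    Fits factor-analytic FA(k) covariance structures for genotype by
    environment effects with heterogeneous residual variances,
    variance-component models with drop-one REML likelihood-ratio
    tests, best linear unbiased predictions (BLUPs), latent-regression
    stability analysis from rotated factor loadings and scores, Cullis
    heritability for unbalanced designs, bivariate genetic
    correlations, carotenoid biofortification arithmetic (provitamin A,
    totals, proportions, benchmark comparisons), and hybrid profiling
    via principal components, Ward clustering and canonical
    discriminant analysis. Includes a synthetic trial generator with
    known factor-analytic ground truth so that every stage can be
    verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
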