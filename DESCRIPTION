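Package: prslife
Title: Polygenic Meta-Scores and Multistate Life Tables for
    Disease-Free Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how genetic risk and lifestyle shape total
    and cardiovascular-disease-free life expectancy. Builds a meta polygenic
    risk score (MetaPRS) for a composite outcome from multiple GWAS summary
    statistics via clumping-and-thresholding candidates, optimal-candidate
    selection, AIC-based ancestry integration, and elastic-net stacking with
    cross-validation. Estimates the three transitions of an illness-death
    model (disease-free to disease, disease-free to other-cause death,
    disease to death) from cohort data using Poisson rate regression,
    five-year age-specific category prevalence, and Cox proportional-hazards
    models, then converts them into group-specific multistate life tables
    over ages 40-90 with Monte Carlo parametric-bootstrap confidence
    intervals for total and disease-free life expectancy. Includes a
    synthetic cohort and genotype generator with Gompertz baseline hazards
    and a continuous-time Kolmogorov-forward-equation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    survival,
    glmnet,
    deSolve,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
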