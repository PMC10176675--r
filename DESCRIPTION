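Package: apcvisits
Title: Age-Period-Cohort Modelling of Health Service Utilisation Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for descriptive Age-Period-Cohort (APC) analysis of
    primary-care visit counts derived from administrative claims records.
    Builds episodes of care from dated claim lines, assembles person-year
    analysis panels linked to survey covariates, and fits a hierarchical
    Poisson model in which a tensor-product P-spline surface over birth
    cohort and calendar period captures the confounded age, period and
    cohort effects while a person-level random intercept absorbs latent
    health-seeking propensity. Includes pooling-variant comparison by
    k-fold expected log pointwise predictive density, reference-person
    prediction and contrast surfaces with pointwise intervals, and a
    synthetic-data generator with known ground truth for end-to-end
    validation. Estimation uses a Laplace-approximate marginal likelihood
    with Fellner-Schall smoothing-parameter selection, or optionally MCMC
    via JAGS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    splines,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    rjags,
    coda,
    yaml
Config/testthat/edition: 3
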