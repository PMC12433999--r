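Package: clustprev
Title: Prevalence Estimation in Clustered Two-Stage Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating disease prevalence from two-stage clustered
    population surveys in which individuals are nested in households,
    households are screened by interviewers, and interviewers work within
    sites. Implements an intercept-only logistic random-intercept model fitted
    by maximum likelihood with adaptive Gauss-Hermite quadrature at the
    household level and a Laplace approximation at the upper levels,
    latent-scale intraclass correlation coefficients, crude and
    cluster-adjusted prevalence per 1,000 with Wald intervals, simulation of
    missing-at-random attrition, sequential k-nearest-neighbour imputation of
    missing binary outcomes, and an experiment driver that crosses attrition
    levels, clustering structures and missing-data handling. A synthetic-data
    generator reproduces the hierarchical structure of a two-site urban
    census so the full pipeline is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
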