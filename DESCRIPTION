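Package: standdyn
Title: Stand Dynamics, Demography and Spatial Association in Stem-Mapped Forest Plots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for repeated stem-mapped forest censuses:
    annualized mortality, recruitment and ingrowth rates with bootstrap
    confidence intervals; size-class mortality bookkeeping across census
    periods; stage-classified matrix population models with dominant-eigenvalue
    population growth rates; bivariate Ripley K12/L12 spatial association with
    torus-shift Monte Carlo envelopes; tree-ring percent-growth-change release
    detection and release chronologies; neighborhood crowding indices with
    exhaustive AIC model selection over random-intercept growth models; and a
    species-trait synthesis (correlations and principal component analysis).
    Includes a synthetic stand and ring-width simulator with known ground truth
    so every stage of the pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
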