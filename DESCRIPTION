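Package: densnest
Title: Territory Density and Nest Survival Analysis for Farmland Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing density-dependent breeding success in
    territorial farmland birds. Computes nearest-neighbour territory density
    metrics from mapped song-post locations, reduces nest-visit histories to
    Mayfield exposure days and stage-specific outcomes, fits
    logistic-exposure daily nest-survival models with covariates, provides
    AICc all-subsets model selection with top-set coefficient averaging and
    marginal/conditional R-squared, projects productivity and survival rates
    into annual population change, and ships a synthetic-data generator that
    reproduces the statistical structure of a two-year organic/conventional
    farm study so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
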