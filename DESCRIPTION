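Package: aidmort
Title: Development-Aid Funding and Mortality in Country Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the association between per-capita
    development-aid funding and all-cause, age-specific and cause-specific
    mortality in multi-country panel data, and for projecting the
    consequences of funding-cut scenarios. Provides fixed-effects Poisson
    (and negative-binomial) estimation with cluster-robust variance,
    counterfactual deaths-averted attribution with Monte-Carlo intervals,
    a two-stage country-level microsimulation forecaster, triangulation
    via propensity-score-matched difference-in-differences with a
    negative-control harness, and a synthetic panel generator with known
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
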