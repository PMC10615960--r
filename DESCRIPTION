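Package: modmedpower
Title: Monte Carlo Power Analysis for Mediation and Moderated Mediation
    with Categorical Exogenous Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation-based (Monte Carlo) power analysis for recursive path
    models whose predictors and moderators are fixed, dummy-coded experimental
    factors.  Specify a population path model with standardized slopes over a
    factorial design matrix, repeatedly simulate samples conditional on the
    fixed design, fit (possibly equality-constrained, multigroup) path models
    by conditional Gaussian maximum likelihood, and test indirect and
    conditional indirect effects -- including the index of moderated
    mediation -- with delta-method Wald tests and Monte Carlo (parametric
    bootstrap) confidence intervals.  Reports empirical power, average bias,
    and coverage per parameter, and sweeps sample sizes for power curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
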