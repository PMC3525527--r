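Package: infertrend
Title: Estimation of Infertility Prevalence Levels and Trends from Survey Microdata
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the prevalence of primary and secondary
    infertility, and exposure to the risk of either, from woman-level
    demographic and reproductive health survey records. Provides a
    synthetic survey microdata generator with known ground truth,
    deterministic classification of respondents into infertile/fertile
    unions and exposure categories, regression-based correction of
    estimates derived from incomplete contraceptive-use or union-duration
    information, a Bayesian hierarchical space-time-age model fitted by
    Markov chain Monte Carlo, population-weighted aggregation of posterior
    draws into regional and global levels, trends with posterior
    probabilities, couples-affected counts, and a country-withholding
    cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
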