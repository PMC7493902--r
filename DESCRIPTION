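Package: ancbayes
Title: Bayesian Multilevel Logistic Models with Historical-Survey Priors for
    Skilled Antenatal Care Uptake
Version: 0.1.0
Authors@R: person(given = "Package", family = "Author",
    email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of pregnancy intention (wanted,
    mistimed, unwanted) on uptake of skilled antenatal care from hierarchical
    household-survey data in the Demographic and Health Survey (DHS) mould.
    Provides a two-stage cluster-survey simulator with a known multilevel
    logistic truth, derivation of the analysis variables (outcome codings,
    media-exposure index, community-level literacy, poverty and care
    aggregates), survey-weighted descriptive statistics and Rao-Scott
    design-corrected chi-square screening, elicitation of per-coefficient
    normal priors from earlier survey waves, survey-weighted random-intercept
    logistic regression fitted by adaptive Gauss-Hermite maximum likelihood
    and by Markov chain Monte Carlo under arbitrary normal priors, and
    Gelman-Rubin, intra-class correlation and AIC/BIC model-comparison
    diagnostics, orchestrated as a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
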