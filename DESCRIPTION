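Package: infovigil
Title: Social-Media Infoveillance of Public Mental Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for tracking public mental health signals
    in social-media streams: lexicon-based identification of mental-health
    tweets in four symptom subgroups (anxiety, depression, insomnia,
    addiction), health-care-worker cohort detection from profile
    descriptions, US-state geography resolution, temporal and geographic
    proportion trends with Wilson confidence intervals, topic modelling via
    collapsed Gibbs sampling for latent Dirichlet allocation with perplexity
    and UMass-coherence model selection, cohort comparison with the exact
    Wilcoxon matched-pairs signed-rank test, and interrupted time series
    (segmented regression) assessment of lockdown policies. Ships a seeded
    synthetic tweet-corpus generator with planted, recoverable effects so
    every stage is testable without platform access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang,
    stringi,
    stats,
    utils,
    sandwich
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
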