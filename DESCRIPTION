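Package: peermod
Title: Moderation of Peer Influence Effects in School Friendship Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how peer influence on
    adolescent smoking and vaping outcomes is moderated by setting,
    intervention programme, gender, school socio-economic status,
    personality characteristics, social network position, and
    self-efficacy. Builds per-school friendship networks from pupil
    nomination rosters; computes the moderating network parameters
    (local clustering, eigenvector, closeness and betweenness
    centralities, and school-level Gini degree coefficients); constructs
    peer-exposure predictors (friend, class and year-group means and
    percent-susceptible analogues); fits grids of moderated linear and
    logistic regressions with Huber-White robust standard errors,
    variance inflation factors, standardized interaction coefficients
    and interaction R-squared increments; probes interactions with
    simple slopes and Johnson-Neyman regions of significance; and
    aggregates evidence per moderator with Holm-Bonferroni adjustment,
    exact one-sided binomial meta-tests and multiverse-style summaries.
    A seeded synthetic cohort generator with homophilous nominations and
    planted peer-influence and moderation effects makes every stage
    testable without access to restricted pupil data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    sandwich,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
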