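Package: modcits
Title: Comparative Interrupted Time Series Evaluation of Social Media Content Moderation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quasi-experimental evaluation of platform content-moderation
    policies from tweet-level records. Builds community-level daily outcome panels
    (relative activity on the logit scale, log Laplace-smoothed retweets per
    follower, minimum-rule URL domain quality, and smoothed topic-category
    shares), detects and imputes server-outage gaps, fits pre-policy SARIMAX
    models with policy-phase dummy regressors, simulates counterfactual
    post-policy forecasts to obtain Z statistics and confidence intervals for
    single series and for treated-versus-comparator contrasts, back-transforms
    effects to odds ratios, relative risks, or additive differences, and fits
    monthly fixed-effects (least squares dummy variable) panel regressions of
    outcomes on lagged moderation-intensity predictors with HAC standard errors
    and residual stationarity diagnostics. A synthetic-ecosystem generator with
    a ground-truth intervention ledger, retweet-network construction with k-core
    decomposition and Louvain community detection, and an end-to-end pipeline
    runner support fully reproducible desk-scale studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    zoo,
    igraph,
    sandwich,
    lmtest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
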