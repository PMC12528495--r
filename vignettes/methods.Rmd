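---
title: "Counterfactual evaluation of content-moderation policies: models, design choices, and what the synthetic studies show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual evaluation of content-moderation policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcits)
```

# The estimation problem

A platform announces a moderation policy on a known date. We observe daily
activity of several account communities before and after, but no community
is a randomised control: every community is exposed to the same news cycle,
the same product changes, and (to varying degrees) the same policy. The
comparative interrupted time series (CITS) design used here asks two
questions separately: did a community deviate from the continuation of its
*own* pre-policy behaviour, and did it deviate *more than* a thematically
matched comparator community that the policy did not target? The first
contrast is vulnerable to contemporaneous shocks; the second absorbs any
shock that hits both communities alike, which is the design's identifying
assumption. It does **not** require parallel paths (the comparator has its
own fitted model), only common shocks.

# Outcome measures

All measures are built per community per day (or calendar month, recomputed
from raw tweet-level data, never averaged from daily values):

* **Relative activity** (`content_logit`): the community's share of all
  tweets that day (retweets and quote records included), logit-transformed.
  Because observed shares can be 0 or 1 in finite samples, counts are
  add-one (Laplace) smoothed, `p = (count + 1) / (total + C)` with `C` the
  number of communities; the smoothing constant preserves closure (shares
  still sum to 1). On the logit scale a multiplicative change in a
  community's volume is an additive shift — exponentiating an average daily
  difference gives an odds ratio.
* **Virality** (`virality_log`): per user-authored tweet,
  `v = log((retweets + 1) / (followers + 1))`; the daily value is the mean
  of `v` over the community's user-authored tweets. The `+1` (Laplace,
  alpha = 1) keeps `v` finite for never-retweeted tweets and zero-follower
  accounts; the natural log is used throughout, so exponentiated
  differences are relative risks.
* **Domain quality** (`quality_mean`): each URL maps to its registered
  domain (public-suffix aware, `www.example.com/... -> example.com`); a
  tweet's score is the *minimum* rating over its rated URLs — a
  conservative rule, since one low-quality link suffices to make a tweet
  low-quality; the daily value is the mean score over rated tweets. Ratings
  live on a linear [0, 1] scale, so effects are reported untransformed.
* **Topic shares** (`topic_logit_*`): topics are grouped by the rater
  unanimity/veto rules (skepticism and promotion require all five raters in
  the respective category set; commentary requires at least one commentary
  label and no skepticism/promotion label), shares are add-one smoothed
  over the four groups, then logit-transformed.

Missing-data handling precedes modelling: a day with zero user-authored
tweets anywhere in the stream is a server outage; the day before and after
each outage run is also dropped (their counts may be partial), and dropped
days are filled by linear interpolation *on the transformed scale*,
independently per community and measure. Interpolation is idempotent and
reproduces any linear segment exactly; gaps touching the span edge carry
the nearest retained value and are flagged. Days bin in UTC.

# The counterfactual engine

Pre-policy spans are fitted with `stats::arima` as a regression with
seasonal ARIMA errors; announced policy phases enter as 0/1 dummy
regressors with inclusive start/end dates. Two conventions matter:

* **Reference regime.** Phase dummies tile the entire pre-period, so one
  dummy is linearly dependent with the intercept. The phase in force on the
  eve of the evaluated policy is taken as the reference: its level is
  absorbed into the intercept, and the forecast horizon (all dummies zero)
  therefore continues the status quo immediately before the policy — which
  is exactly what "no policy change" should mean. A rank check drops any
  further collinear regressors by QR pivoting and records them.
* **Counterfactual dummies.** The evaluated policy's own dummy is held at
  zero over the horizon (it is all-zero in the pre-period, so it never
  enters the fit); earlier phases keep their actual (expired) values.

Order selection is either fixed or a stepwise AIC search in the spirit of
automatic ARIMA selection: standard starting candidates, one-step
neighbour moves over (p, q)(P, Q), caps at p, q <= 5 and P, Q <= 2,
first differencing applied when an augmented Dickey-Fuller test cannot
reject a unit root. Non-convergent fixed-order fits walk a retry ladder
(ML with CSS starting values, pure CSS, d + 1, then AR(1)), and every
fallback is recorded in the fit object.

Forecast simulation expands the fitted model into its full autoregressive
lag polynomial (nonseasonal x seasonal x differencing) and moving-average
polynomial, then iterates the recursion forward from the tail of the
regression-adjusted history, feeding fitted innovations into the MA terms
and drawing new innovations from N(0, sigma_hat^2). Parameters are held at
their estimates; no parameter uncertainty is propagated. This matches the
simulated-forecast contract of the statistic (below) and is verified, in
the test suite, against an independent brute-force AR(1) recursion at the
fitted parameters.

For each of B simulated paths the horizon mean `M_k` is recorded;
`m_hat_k` and `s_hat_k` are the Monte-Carlo mean and SD. The single-series
statistic is `Z = (mean(y_obs) - m_hat_k) / s_hat_k` with CI
`mean(y_obs) - m_hat_k +/- z_crit * s_hat_k`; by construction the CI
excludes zero exactly when `|Z| > z_crit`, at any alpha. The comparative
statistic subtracts the comparator's deviation and, by default, pools the
two forecast variances by **summation** — the variance of a difference of
independent estimates adds. A printed-form variant with a differenced
denominator `sqrt(s_anti^2 - s_pro^2)` is provided for completeness; it is
not a valid variance in general and raises an explicit
degenerate-denominator error whenever the difference is not positive, so
it cannot fail silently. Multiple-comparison correction (Bonferroni across
pairs, off by default) acts on `z_crit` and is recorded in the output
attributes.

## A calibration property worth knowing

Because the simulated paths condition on the *estimated* parameters, the
spread `s_hat_k` measures forecast uncertainty but not estimation
uncertainty in the fitted mean structure. The variance of the Z statistic
under the null is therefore inflated by a term of order `k/n` (times a
factor growing with the AR persistence), where `n` is the pre-period
length and `k` the horizon. In synthetic null studies the empirical type-I
error at 1.96 is close to nominal when `n` is large relative to `k`
(roughly `n/k >= 20` at the persistence levels used here) and drifts to
8–15% when the horizon is long relative to the fit span. The package's
calibration studies therefore use pre-periods of 550–600 days with
horizons of 14–20 days. Users evaluating long post-policy phases with
short pre-periods should expect anti-conservative intervals; the
comparative statistic inherits the same property, plus a mild dependence
on how strongly the treated and comparator communities share the
denominator of the share measure (see below).

# The synthetic ecosystem

The generator exists so that every downstream stage has an input with
*known* ground truth. It emulates the structure the estimators assume:

* ~25 communities (configurable) with heterogeneous baseline volumes
  (log-spaced 500 down to 50 tweets/day by default), observed from
  2020-02-07 for 1045 days by default;
* daily user-authored volume `Poisson(lambda_ct)` with
  `log lambda_ct = log(baseline_c) + s_ct + A sin(2 pi t / 7)`, where
  `s_ct` is a stationary AR(1) (phi = 0.6, innovation SD 0.15) and the
  weekly sinusoid (amplitude 0.15) is shared across communities, as
  weekday rhythms are;
* log-normal follower counts (meanlog 7.5, sdlog 1 — median ~1800,
  heavy-tailed), Poisson retweet counts with mean
  `retweet_rate x followers` modulated by a day-level AR(1) news-cycle
  factor (phi = 0.5, SD 0.1), with a negative-binomial dispersion knob for
  heavier tails;
* URLs drawn from a rated domain pool through a community-specific
  exponential tilt on quality — quality interventions re-solve the tilt so
  the *expected* mean quality shifts by exactly the requested additive
  amount;
* topic labels from per-community category mixtures; retweet records that
  inherit the original tweet's URL and topic; outage days with no records;
* step interventions with multiplicative volume and retweet-rate effects
  and additive quality effects, all recorded in a ground-truth ledger that
  downstream tests read instead of re-deriving truth from the stream.

All randomness flows from one root seed through keyed substreams
(`substream_seed`) per community and per community-day, so any slice can
be regenerated in isolation and identical configurations are byte-identical.

What the generator does **not** emulate: burstiness beyond AR(1)
(cascades, exogenous news shocks), follower growth over time, coordinated
or automated accounts, topic drift, and any dependence of retweet counts
on content. Passing recovery tests therefore show that the estimators
recover effects *under the model class they assume*, not that real
platform data satisfy those assumptions.

Three quantitative consequences of the generative choices are worth
stating because the recovery studies in the test suite depend on them:

* **Virality truth is slightly attenuated.** The injected rate effect
  multiplies the Poisson retweet mean, but the measure is
  `E log(retweets + 1)`; smoothing compresses a 1.4-fold rate increase to
  about a 1.39-fold measured relative risk at the default follower and
  rate settings (computed by direct numerical integration). The recovery
  bands in the tests are wide enough that this is immaterial, but exact
  equality should not be expected.
* **Share measures couple communities.** One community's volume shock
  enters every other community's denominator. The comparative odds ratio
  for a volume effect is therefore biased slightly *away* from the null
  (the comparator's share falls when the treated community grows), by
  `log(1 + a/(1-b))` on the log-odds scale for treated share `a` and
  comparator share `b`. Recovery studies use small treated/comparator
  communities beside large bystander communities so this term (~0.05) is
  well inside the interval width.
* **Cross-community retweet records couple quality panels.** When retweet
  records cross communities they carry foreign URLs into the local quality
  mean, so a volume intervention changes the *composition* of a
  community's quality panel in addition to any quality intervention.
  Studies that want ground-truth quality effects to be exact set
  `within_community_prob = 1`; the default (0.9) keeps the realistic
  coupling for everything else.

# Fixed-effects panel analysis

`build_panel` aligns monthly outcomes at month *t* with platform-wide
transparency counts at *t - 1* (guarding against enforcement intensity
responding to contemporaneous misinformation) and adds a first-order
lagged outcome; with predictors spanning July 2020 – September 2022 the
outcome rows span August 2020 – October 2022. `fit_lsdv` estimates the
least-squares dummy-variable regression with one reference community
dropped (recorded in the fit), optional community x predictor
interactions, and Newey-West HAC standard errors with the automatic lag
rule `floor(4 (T/100)^{2/9})`. Known properties, both exercised in tests:
without interactions and lagged outcome, the LSDV point estimates equal
the within (demeaned) estimator to numerical tolerance; with a lagged
outcome the usual Nickell bias appears at small T (about −0.08 on an
autoregressive coefficient of 0.3 at T = 27) and vanishes as T grows.

Residual stationarity is assessed by an augmented Dickey-Fuller test
(constant, no trend; lag order `trunc((n-1)^(1/3))` by default) written
against the classical tabulated Dickey-Fuller distribution with bilinear
interpolation in sample size and probability, p-values clamped to
[0.01, 0.99]. The test statistic agrees with the reference implementation
in `statsmodels` to six decimals on fixed series; the interpolated
p-values agree to within ~0.02. Series shorter than 12 observations or
with (numerically) zero variance report an `inconclusive` verdict rather
than failing. The pooled verdict is majority rule over testable series.

# Network module

The retweet network connects retweeter to original author (credit flows to
the author; the direction is recorded, and the degree test is undirected
either way), with integer arc weights counting retweets. The k-core
(default k = 3) keeps accounts connected to at least k *distinct* others,
ignoring direction and multiplicity; a weighted-degree variant is
available by flag. Community extraction is Louvain on the collapsed
weighted graph, deterministic given a seed; the number of communities is
data-dependent and never asserted on synthetic graphs. Per-community
activity lists rank accounts by tweet count with lexicographic
tie-breaking, top 25 retained.

# Numerical and testing choices

* Interval arithmetic is exact algebra; the only tolerances in the test
  suite are Monte-Carlo (3 standard errors for oracle equivalence) and
  1e-8 for the fixed-effects identity.
* The synthetic studies in the test suite use: 300 null replicates
  (four communities, 614 days, 14-day horizon) for type-I calibration;
  100 recovery replicates (four communities, 540 days, 30-day horizon,
  injected odds factor 2.0, rate factor 1.4, quality shift −0.07) for
  effect recovery and CI coverage; B = 300–400 simulated paths per fit in
  those studies and B = 1000 for the single oracle-equivalence check.
  These sizes keep each study's Monte-Carlo error comfortably below the
  tolerance it is checked against.
* The stepwise order search evaluates a handful of models per series;
  white-noise inputs may select small non-null ARMA orders when AIC
  marginally prefers them — the innovation variance, not the order, is the
  contract tested.
* `as_printed` pooling, zero forecast spread (`s_hat = 0`), horizon
  mismatches, all-dropped series, rank-deficient panels, and gapped
  transparency tables all raise explicit errors naming the offending
  quantity; they are never silently repaired.

# Known limitations

* The Z statistic's anti-conservatism at large `k/n` (above) is a property
  of the simulated-forecast method itself, not of this implementation.
* Odds-scale effects on shares are only approximately community-local;
  with few communities of comparable size the coupling term is not
  negligible.
* The ADF p-values interpolate a coarse classical table; inference within
  ~0.02 of a chosen threshold should not be over-read.
* Quote tweets are not modelled distinctly from retweets, and accounts are
  not typed (human, institutional, automated).
* The generator's transparency table is a stylised intensity series, not a
  calibrated model of platform enforcement reporting.
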