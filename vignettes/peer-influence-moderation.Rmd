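---
title: "Moderation of peer influence in school friendship networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderation of peer influence in school friendship networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peermod)
```

## The analysis

`peermod` implements a moderation-of-peer-influence analysis for school
cohort studies of adolescent smoking and vaping. Pupils in a school year
group name up to ten friends; outcomes (experimentally elicited and
self-reported social norms, smoking behaviour, intentions, attitudes,
self-efficacy, perceived risks and benefits, carbon-monoxide readings, and
a binary susceptibility flag) are measured at baseline and follow-up. The
question is not whether peers matter but *for whom they matter more*: is
the association between a pupil's follow-up outcome and their peers'
average outcome stronger in one setting than another, for girls than boys,
for pupils with particular personality profiles, or for pupils occupying
particular network positions?

For focal pupil $i$, outcome $y$, peer group $g$ (nominated friends, school
class excluding $i$, or school year group excluding $i$) and wave $t$ of
peer measurement, the peer-exposure predictor is the mean of the
contributing peers' values, $\bar{x}^{(g,t)}_i$ (a percentage for the
binary outcome). Each model in the grid is

$$
y_{i1} = \beta_0 + \beta_1 \bar{x}^{(g,t)}_i + \beta_2 w_i +
\beta_3\, \bar{x}^{(g,t)}_i w_i + \gamma' z_i + \beta_4 y_{i0} +
\varepsilon_i,
$$

fitted by OLS with Huber–White (HC1) robust standard errors, or the
logistic analogue with robust standard errors for susceptibility. $w_i$ is
the moderator (0/1 for dichotomous moderators, mean-centered for
continuous ones), $z_i$ the baseline covariates (gender, age band,
intervention, ethnicity, individual SES as indicator contrasts), and
$y_{i0}$ the mean-centered baseline outcome. Continuous predictors are
mean-centered on the estimation sample after listwise deletion, and the
product term is formed after centering. A model counts as evidence of
moderation when the interaction term reaches $p \le 0.01$.

One moderator's grid spans 46 outcomes x 3 peer groups x 2 waves = 276
models (the three self-efficacy subscale moderators exclude the three
self-efficacy outcomes: 258 each, 774 combined; single-setting
friends-only reruns give 46 x 2 = 92). Because no single model is
interpretable at that multiplicity, evidence is aggregated per moderator:

* counts and percentages of significant interactions, split by direction
  (sign of $\beta_3$, mapped to the moderator's substantive labels);
* an exact one-sided binomial meta-test $P(X \ge k)$, $X \sim
  \mathrm{Bin}(n, 0.01)$, for the total and for each directional count,
  always against the full grid size $n$;
* Holm–Bonferroni step-down flags at a family level of 0.05;
* multiverse-style summaries: the p-value distribution, volcano
  coordinates $(\beta_3^{std}, -\log_{10} p)$ with the standardized
  interaction coefficient $\beta_3^{std} = \beta_3\,
  \mathrm{SD}(\bar{x}) / \mathrm{SD}(y)$, per-cell grids, and heatmap
  percentages per outcome family.

Significant interactions are probed with simple slopes
($\beta_1 + \beta_3 w$, with variance
$\mathrm{var}(\beta_1) + w^2 \mathrm{var}(\beta_3) +
2w\,\mathrm{cov}(\beta_1, \beta_3)$ from the robust covariance, evaluated
at the two levels of a dichotomous moderator or at $\pm 1$ SD of a
continuous one) and with Johnson–Neyman regions of significance at the 95%
and 99% levels, whose boundaries are the real roots of a quadratic in $w$
within the observed moderator range.

## Network moderators

Five network parameters act as moderators, computed per school and wave
from the undirected **union** projection of the nomination graph (an edge
if either pupil names the other; the symmetrization rule is configurable
and recorded in output metadata, since elicited friendship data do not
dictate one):

* local clustering coefficient (closed neighbour pairs / possible pairs);
* eigenvector centrality: the leading eigenvector of the adjacency matrix,
  computed by shifted power iteration to a relative tolerance of $10^{-10}$
  and normalized to unit Euclidean norm. In disconnected school networks
  the result is the limit of power iteration from a uniform positive
  start, so mass concentrates on the component(s) with the largest leading
  eigenvalue and other nodes score ~0 — a documented convention, since no
  normalization of eigenvector centrality across components is canonical;
* Wasserman–Faust component-adjusted closeness,
  $\frac{r-1}{\sum d}\cdot\frac{r-1}{n-1}$ over the $r$ reachable nodes,
  which keeps scores comparable across fragmented networks;
* shortest-path betweenness normalized by $(n-1)(n-2)/2$;
* the school-level Gini coefficient of the degree sequence,
  $G = \sum_{ij} |d_i - d_j| \,/\, (2 n^2 \bar{d})$, a heterogeneity
  measure (0 iff the network is degree-regular).

All five are reported **x10**. That scaling, and the unit-norm eigenvector
convention, reproduce the magnitudes conventional for these instruments
(clustering on a 0–10 scale with cohort means around 3–4, closeness around
3.5–4, Gini around 2); both are single switches (`scale10 = FALSE`)
because neither affects model fits beyond the scale of $\beta_2, \beta_3$.
Isolates receive 0 on all four node metrics. Peer exposure always uses
directed out-neighbours (the friends the focal pupil named), independent
of the symmetrization used for centralities; whether elicited friendship
networks should be read as directed for exposure is itself a judgement
call, and out-nomination is the variant that matches "the pupils $i$
considers friends".

## The synthetic cohort generator

Real school-cohort data of this kind are access-restricted, so the package
ships a seeded generator that emulates the cohort structure the analysis
assumes and makes every downstream stage testable: 12 schools in two
settings (NI / Bogota), 55 classes, ~1,375 pupils, two intervention
programmes allocated within setting, pupil attributes (gender, age band,
ethnicity, ordinal SES), nine personality moderators drawn truncated-normal
within their instrument ranges, school deprivation scores quartiled into an
ordinal school SES, and 46 outcomes with baseline means/SDs matching the
field's instruments.

Nominations are drawn per pupil with out-degree $\mathrm{Bin}(10, m/10)$
(cap 10 by construction, default mean $m = 5$), sampling schoolmates
without replacement with weight multipliers 8 for same-class and 3 for
same-gender candidates — strong class homophily and moderate gender
homophily, the two best-documented regularities of adolescent friendship
nomination. Wave-1 nominations are an independent draw from the same
model; friendship co-evolution is out of scope.

Follow-up outcomes follow a linear autoregressive process with planted
peer influence and moderation:

$$
y_{i1} = b_0 + b_{base} y_{i0} + b_{peer} \bar{x}_i + b_{mod} w^c_i +
b_{int}\, \bar{x}^c_i w^c_i + \varepsilon_i,
$$

with $\bar{x}_i$ the friend out-neighbour mean at baseline (lagged
influence), $w^c$ and $\bar{x}^c$ population-centered so the fitted
interaction coefficient estimates $b_{int}$ directly, and
$\varepsilon_i \sim N(0, (\texttt{noise\_scale} \cdot \sigma_{y0})^2)$.
Results are **truncated** to the outcome's scale bounds rather than
resampled, preserving the linear interpretation in the interior of the
scale. The per-outcome intercept is set to
$(1 - b_{base} - b_{peer})\mu_{y0}$ so follow-up means track baseline
means. The binary susceptibility outcome uses the logistic analogue with a
standardized percent-susceptible predictor. Follow-up missingness is
completely at random (default 7%, matching the high completion such
studies report); no informative-missingness machinery is included.

Defaults, chosen once: $b_{base} = 0.5$, $b_{peer} = 0.25$,
$b_{mod} = 0.1$, $b_{int} = 0.1$ on pro-sociality,
$\texttt{noise\_scale} = 0.6$. These give autoregression, peer influence
and moderation of the moderate magnitudes such cohorts show, with planted
effects recoverable at the default cohort size.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: triadic closure beyond class/gender homophily
(generated clustering coefficients run lower than real friendship
networks), selection homophily on outcomes (peers are not more similar at
baseline than chance within class), item-level survey structure (scale
scores are drawn directly; `generate_item_responses()` exists to exercise
reliability computations), and any informative missingness.

## Numerical and design choices

* **HC1** is the default robust variant because the analyses this package
  operationalizes are conventionally run in software whose default robust
  estimator is HC1; HC0/HC3 are available. Linear-model p-values use
  $t_{n-k}$; logistic Wald tests use the normal.
* Probing uses the same robust covariance as fitting, for internal
  consistency. For logistic models, slopes and Johnson–Neyman regions are
  computed on the log-odds scale, where the Wald machinery is exact.
* Johnson–Neyman boundaries are reported only within the observed
  moderator range; roots outside it are flagged as extrapolated. The
  degenerate case $b_3 \approx 0$ collapses to constant significance.
* VIFs are $1/(1 - R^2_j)$ via the inverse predictor correlation matrix,
  with flags at 5 and 10; perfectly collinear designs are an error naming
  the columns (linear) and exactly singular covariates are reported as
  infinite.
* Covariates that are constant on an estimation sample (e.g. intervention
  within a single-programme school subset) are dropped from that model
  rather than allowed to make the design singular.
* Unfit models (rank deficiency, perfect separation, insufficient rows)
  stay in the grid denominator as non-significant, because the summary
  table's denominators are fixed grid sizes.
* Quartiling of school deprivation uses inclusive linear-interpolation
  quantiles (R type 7); boundary ties fall to the lower bin; orientation is
  1 = most deprived (lowest SES) by default and configurable, since
  deprivation measures differ in direction.
* The binomial meta-test sums the exact binomial mass in log space;
  Holm–Bonferroni is the standard step-down with cumulative-maximum
  monotonicity.

## What the test suite establishes, and at what scale

Unit oracles: network metrics against dense eigen-decomposition,
Floyd–Warshall distances, and shortest-path-count betweenness on every
labelled graph with up to 4 nodes plus seeded random graphs up to 8 nodes;
OLS/HC1 against explicit matrix algebra on 1,000 random small designs;
logistic coefficients against closed-form 2x2 log odds ratios;
Johnson–Neyman boundaries against a $10^5$-point scan of the conditional
t-statistic on 100 random fits; Holm against the reference step-down
adjustment on 1,000 random p-vectors; Cronbach's alpha against its
exchangeable-covariance closed form.

Simulation checks are scaled to run in minutes, with sizes stated here as
the package's own choices: type-I calibration uses 200 null-replicate
grids of 12 distinct outcomes (friend exposure at baseline) on
default-scale cohorts — distinct outcomes carry independent noise, so the
meta-test's independence premise holds by construction; parameter recovery
plants $b_{int} \in \{0.1, 0.3, 0.5\}$ at $n = 2{,}000$ over 200 seeds per
effect and requires $|\mathrm{bias}| < 2\,\mathrm{MCSE}$ plus monotone
meta-test power.

## Known limitations

* Robust-t interaction tests are asymptotic: in cohorts of a few hundred
  pupils their finite-sample size at the 1% criterion runs slightly above
  nominal (the product regressor is kurtotic), which is a property of
  sandwich inference, not of this implementation. At the default cohort
  scale the empirical size is ~1%.
* The binomial meta-test treats the grid's models as independent. Models
  sharing an outcome across peer groups and waves are positively
  correlated, so on full 276-model grids the meta-test is mildly
  anti-conservative — a caveat that applies equally to the analysis design
  this package operationalizes.
* Group-level moderators (setting, school SES, Gini) interact with
  class/year exposures that are nearly constant within school; such models
  can show high VIFs and can absorb school-level structure under nonzero
  peer effects. The grid flags VIFs above 5 and 10 per model.
* No multilevel/random-effects modelling, no stochastic actor-oriented
  network co-evolution, no selection-vs-influence decomposition: the
  package quantifies moderation of association, not causal peer effects.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  seed = 1,
  moderators = c("setting", "gender", "pro_sociality", "eigenvector"),
  outcomes = c("p2s2", "exp_injunctive_scale", "intentions",
               "susceptibility"))
bundle <- run_pipeline(cfg)
summary_table(bundle$summaries)
bundle$probes[[1]]$slopes      # simple slopes for one probed interaction
bundle$probes[[1]]$jn95        # 95% region of significance
```
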