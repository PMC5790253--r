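---
title: "Methods: BACI evaluation of marine reserve effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BACI evaluation of marine reserve effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpaeval)
```

## The evaluation problem

A no-take marine reserve is created to meet stated management objectives —
recovering overexploited stocks, preserving biodiversity, improving fishery
production in adjacent waters. Whether it does so cannot be read off a
single survey: fish and invertebrate populations drift with climate and
recruitment everywhere, inside and outside the reserve. The question is
causal, and the sampling design that supports a causal answer is
before-after-control-impact (BACI): annual underwater visual-census
transects in the reserve and in a comparable fished control site, starting
before implementation.

`mpaeval` turns such monitoring data into a difference-in-differences (DiD)
estimate of the reserve effect per indicator, and summarizes the estimates
in a color-coded scorecard.

## The model

For each numeric biological indicator, the per-transect value $I_{i,t,z}$
(transect $i$, year $t$, zone $z$) is modeled as

$$I_{i,t,z} = \beta_0 + \sum_{t \ge 2} \gamma_t Y_t + \beta_1 Z_{i,z}
  + \beta_2 P_{i,t} \times Z_{i,z} + \beta_3 T_{i,t,z} + \beta_4 V_{i,t,z}
  + \beta_5 D_{i,t,z} + \epsilon_{i,t,z}$$

with years as factor dummies $Y_t$ (first survey year as reference, so no
linear time trend is imposed), treatment dummy $Z$ (control = 0, reserve =
1), post-implementation dummy $P$ (before = 0, after = 1), and survey
covariates: bottom temperature $T$ (°C), horizontal visibility $V$ (m) and
depth $D$ (m). The reserve effect is the interaction coefficient
$\beta_2$ — the difference between the temporal change in the reserve and
the temporal change in the control. A standalone $P$ main effect is
deliberately absent: the year dummies span it, and including it would make
the design singular.

Coefficients are estimated by OLS and inference uses
heteroskedasticity-robust (sandwich) standard errors,
$(X'X)^{-1} X' \,\mathrm{diag}(w_i e_i^2)\, X (X'X)^{-1}$. All four
classical weightings HC0–HC3 are exposed; the default is HC1
($w_i = n/(n-k)$), the common small-sample convention. Ecological count
data are strongly overdispersed and their variance scales with the mean,
which differs between zones and years — exactly the situation robust
standard errors are for. The no-change null $H_0\!: \beta_j = 0$ is tested
with a Student-t statistic on $n - \mathrm{rank}(X)$ degrees of freedom.

Economic series (annual landings and income) typically have no control
site, so they are evaluated with the before-after reduction
$I_t = \beta_0 + \beta_1 P_t + \epsilon_t$: $\beta_1$ is algebraically the
difference between the post- and pre-period means. These fits are flagged
non-causal throughout — without a control, a coast-wide trend is
indistinguishable from a reserve effect.

### Numerical choices and degenerate inputs

* The design matrix is checked for full rank with a QR decomposition
  before fitting; a deficiency is an error that names the collinear
  columns rather than silently dropping them.
* Rows with missing covariates are removed listwise with the count logged.
  When more than half the rows would be lost, the model falls back to the
  covariate-free specification instead (losing the adjustment is better
  than losing most of the data); the fallback is logged.
* A zero robust standard error (possible on exact, noise-free input)
  yields an infinite t statistic with p = 0 rather than NaN.
* Transects where an indicator is undefined (Shannon diversity with no
  organisms, biomass with no measured lengths) are excluded from that
  indicator's fit, never entered as zeros: "not measurable" and "absent"
  are different facts, and conflating them biases $\beta_2$.
* `post_from` decides whether the implementation year itself counts as
  "after" (`impl-year`, the default) or not (`impl-year+1`); a reserve
  implemented mid-season makes either convention defensible, so it is a
  flag rather than a hard-coded rule.

## Indicators

Per-transect biological indicators, computed separately for the fish and
invertebrate communities (and per target species where marked):

| Code | Indicator | Unit | Needs traits |
|---|---|---|---|
| B1 | Shannon diversity index $-\sum p_s \ln p_s$ | nats | no |
| B2 | Species richness | species/transect | no |
| B3 | Density of mature organisms | % of measured organisms | maturity length |
| B4 | Density (also per target species) | organisms/transect | no |
| B6 | Mean trophic level | – | trophic levels |
| B7 | Biomass $\sum a_s L^{b_s}$ (also per target species) | kg/transect | length–weight |

Conventions worth stating because the indicator names alone do not fix
them: the Shannon index uses the natural logarithm; biomass uses the
universal fisheries allometry $W = aL^b$ with $a$ in g·cm$^{-b}$ and no
silent default coefficients; B3 is reported as a percent with ties at the
maturity length counting as mature; mean trophic level is
abundance-weighted (biomass weighting would couple B6 to the length–weight
traits and their errors, so the simpler convention was chosen and is
stated here). Length-structured indicators (B3, B6, B7) are computed for
fish, whose total lengths are recorded by visual census protocols.
Transect dimensions vary between monitoring programs, so all indicators
are per transect; per-area standardization is left to the user.

Monetary series are deflated with a consumer price index before the
before-after fit. The adjustment is implemented as income $\times\,
\mathrm{CPI}_t / \mathrm{CPI}_T$ with $T$ the reference (most recent)
year, which is the form the workflow standardizes on; because the
conventional constant-currency deflator is the reciprocal ratio, a
`deflation = "standard"` switch applies income $\times\,
\mathrm{CPI}_T / \mathrm{CPI}_t$ instead. The direction is ambiguous in
parts of the applied literature, so it is an explicit, documented switch
rather than a guess.

## Scorecard

Objectives map to indicators through a fixed objective–indicator matrix
(`indicators_for_objectives()`); governance indicators are attached to
every objective, as each is a plausible explanatory variable for reserve
performance. Each numeric indicator is colored by the sign of its effect
coefficient and the significance band of its t test: p < 0.05 dark
green/red, p < 0.1 green/red, otherwise yellow regardless of sign.
Governance responses are scored binary red/green against an editable
rubric; descriptive codes pass through to the report unscored.

Category and global scores are the percentage of positive indicators
among the scored ones. The default counts an indicator as positive when
its effect direction is positive, regardless of significance — the
counting rule is stated without a significance qualifier and yellow
indicators still carry a sign. A `scoring = "strict"` mode counts only
positives significant at p < 0.1, for users who want the score to track
the colored (non-yellow) cells; the default is the permissive rule.

The shipped governance rubric
(`inst/extdata/governance_rubric_synthetic.csv`) is a reconstruction
written for this package from published summaries of how governance
factors relate to reserve outcomes; it is not a copy of any original
scoring table, every row carries a note with its reasoning, and
`governance_rubric(path)` accepts a locally validated replacement. Two
rows are genuinely judgment calls a user may want to flip: a *neutral*
perceived effectiveness or social impact is scored red here (no perceived
benefit does not sustain support), and *medium* representation is scored
green.

## The simulator

The simulator exists so that every stage can be tested against known
ground truth. It emulates the BACI data-generating process the DiD model
assumes: a species pool with per-transect mean abundances, shared
(zone-independent) log-scale year shocks — so parallel trends hold by
construction — per-transect environmental covariates, and an injected
additive post×reserve shift in expected total density per taxon group,
which *is* the true $\beta_2$ for the density indicator. Counts are
negative-binomial (field counts are overdispersed, which is precisely
what the robust-SE machinery must absorb); a rounded-Gaussian
homoskedastic option exists for clean calibration checks of the t test.
Fish lengths are Gaussian around a species mean; empty transects are
written with the reserved `NONE` code so that zero densities survive the
round trip through CSV.

What the simulator does **not** emulate: spatial structure within sites,
habitat covariate effects on abundance, observer effects, and temporal
autocorrelation beyond the shared year shock. Passing tests therefore
show that the estimator recovers effects under the model's own
assumptions at realistic sample sizes — they do not show robustness to
violations (e.g. non-parallel trends), which no within-package simulation
could certify.

Default study conditions follow the sampling guidance for this design:
at least 12–16 transects per site per year (12 per site-year is the
recommended minimum, giving 48 samples in the smallest two-year design),
and the decade-scale preset uses 11 survey years with 12–27 transects per
site-year, a fish community plus four harvested invertebrates. Simulation
checks in the test-suite use 2,000 replicates for the null-calibration
check of the $\beta_2$ test at the minimum design size, and 500
replicates for bias and 95%-CI coverage at the decade scale — sizes at
which Monte-Carlo error is small relative to the accepted bands.

## Limitations

* Reserves without a control site or without pre-implementation surveys
  cannot be evaluated causally; the design check fails hard, and the
  before-after economic model never claims causality.
* Standard errors are heteroskedasticity-robust but not clustered; the
  model has no transect-level random effects and no spatial
  autocorrelation structure.
* Governance scoring is a literature-informed lookup, not an analysis:
  the numbers in the governance category summarize the rubric, not the
  data.
* Indicator values are per transect; comparing absolute magnitudes across
  monitoring programs with different transect dimensions requires
  external standardization.
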