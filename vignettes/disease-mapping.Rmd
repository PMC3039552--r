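---
title: "Bayesian small-area smoothing of cancer incidence and relative survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian small-area smoothing of cancer incidence and relative survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiatlas)
```

## The problem

Cancer atlases report, for each of hundreds of small geographical areas, how
an area's cancer incidence and survival compare with the regional average.
Raw small-area statistics are unusable for this: an area with two expected
cases swings wildly with every extra diagnosis, and an area with none gets a
standardised incidence ratio of exactly zero. The standard remedy is Bayesian
spatial smoothing — each area borrows strength from its neighbours, so
estimates in sparse areas shrink toward their local surroundings rather than
jumping to extremes.

`epiatlas` implements that full analytical pipeline: neighbourhood
construction, expected-count and person-time preparation, two hierarchical
models fitted by MCMC, convergence screening, a global clustering test,
stratum-level aggregation of posterior draws, and five-class map
classification — plus a synthetic registry-data generator so the whole
pipeline can be validated end to end without access to confidential registry
records.

## Models

### Incidence: the BYM model

For areas $i = 1,\dots,n$ with observed counts $y_i$ and expected counts
$e_i$ (indirect standardisation against the pooled age- and sex-specific
rates, so $\sum_i e_i = \sum_i y_i$ within a sex):

$$y_i \sim \text{Poisson}(e_i \theta_i), \qquad
\log \theta_i = \alpha + u_i + v_i.$$

$\theta_i$ is the smoothed SIR, $\alpha$ the overall log relative risk
(prior $N(0, 10^{10})$), $v_i \sim N(0, 1/\tau_v)$ exchangeable noise, and
$u_i$ a spatially structured effect under the intrinsic CAR prior

$$u_i \mid u_{-i} \sim N\!\Big(\tfrac{1}{n_i}\textstyle\sum_{j \sim i} u_j,\;
\tfrac{1}{\tau_u n_i}\Big),$$

equivalently a joint density $\propto \tau_u^{(n-c)/2}
\exp\{-\tfrac{\tau_u}{2}\sum_{i \sim j}(u_i-u_j)^2\}$ on the sum-to-zero
subspace ($c$ = number of graph components). Adjacency $i \sim j$ is
first-order queen contiguity: areas sharing any boundary point, edge or
corner. Islands must first be linked into the graph (`repair_isolates()`,
nearest-centroid by default, manual grouping as the fidelity escape hatch)
because an area without neighbours cannot be smoothed at all.

### Relative survival: the spatial excess-mortality model

Survival is modelled on collapsed person-time cells indexed by broad age
group at diagnosis $k$, follow-up year $j = 1..5$ and area $i$: person-years
$y_{kji}$, observed deaths $d_{kji}$, and expected background deaths
$d^*_{kji}$ from a population life table. Deaths follow

$$d_{kji} \sim \text{Poisson}(\mu_{kji}), \qquad
\log(\mu_{kji} - d^*_{kji}) = \log(y_{kji}) + \alpha_j + \beta_k + u_i + v_i,$$

so each cell's mean is its background mortality plus a piecewise-constant
excess hazard — the mortality attributable to the cancer, without needing
cause-of-death coding. $\mu > d^*$ holds for every admissible state by
construction of the link. The smoothed relative excess risk is
$\text{RER}_i = \exp(u_i + v_i)$. $\alpha_j$ and $\beta_k$ get $N(0, 10^6)$
priors; the youngest broad age band is the reference with $\beta_1 = 0$
(all $\alpha_j$ are left free, so one $\beta$ must be pinned to identify
them). Cells with zero person-time carry no
information and break the offset, so they are dropped from the likelihood.

### Hyperpriors

Six candidate hyperprior pairs per model ship as presets
(`incidence_prior()`, `survival_prior()`), either Gamma on the precision
$\tau$ or Uniform on $\sigma = 1/\sqrt{\tau}$. The production defaults are
preset 3 in both families: incidence $\tau_u \sim \Gamma(0.1, 0.1)$,
$\tau_v \sim \Gamma(0.001, 0.001)$; survival $\tau_u, \tau_v \sim
\Gamma(0.1, 0.01)$ — the pair that sensitivity analysis favours for
plausible, convergent results across cancers. `model_fit_stats()` reports
the comparison statistics used there: pD and DIC (Spiegelhalter
definitions, deviance evaluated with the plug-in at the posterior means of
$\alpha, u, v$), the spatial fraction (posterior mean of
$\mathrm{sd}(u)/(\mathrm{sd}(u)+\mathrm{sd}(v))$ per draw), and the 90%
ratio (95th/5th percentile of the per-area posterior-median map). The
spatial-fraction and 90%-ratio conventions are this package's declared
definitions; there is no single standard form for either.

## Computation

Fitting is single-chain Metropolis-within-Gibbs, coded in C++ (Rcpp) with
R's RNG so every run is reproducible from `set.seed()`: random-walk MH for
the intercept(s) and every $u_i$, $v_i$; conjugate Gamma Gibbs updates for
precisions under gamma priors and MH on $\log\sigma$ under uniform-on-sigma
priors. After every sweep $u$ is re-centred to sum to zero with the shift
absorbed into the intercept — the standard identifiability convention for
intrinsic CAR models, exact because the intercept priors are vague.
Proposal scales adapt by Robbins-Monro toward 44% acceptance during burn-in
only, so the kept chain is a fixed Markov kernel.

The production schedule (`mcmc_production_scale()`) is a 100,000-sweep burn-in
for incidence models and 250,000 for survival models, followed by 100,000
sweeps thinned by 10 — 10,000 stored draws. The desk schedule
(`mcmc_desk_scale()`, 5,000/5,000/5) is for interactive work; tests in this
package mostly use 10,000/10,000/10, which a laptop-class CPU completes in
seconds even at a few hundred areas.

### Convergence screening

`geweke_z()` compares the mean of the first 1,000 stored draws with the
mean of the last 5,000 (10% and 50% of a 10,000-draw chain), scaled by the
asymptotic standard error of the difference; each window's long-run
variance is the spectral density at zero from an AIC-selected AR fit (order
capped at 30), the diagnostic's canonical estimator. Areas with $p < 0.01$
are flagged as unlikely to have converged. `convergence_report()` also
emits trace, density and autocorrelation tables for a plot sample of about
5% of areas — half the lowest-count areas (where mixing problems
concentrate), topped up by a seeded random selection. The small-number rule
has no canonical threshold; taking the lowest-count half is this package's
documented choice, with the fraction configurable.

## Is the mapped variation real?

`tango_meet()` answers globally with the maximised excess events test. For
modelled observed values $O_i$ (smoothed SIR $\times e_i$ for incidence;
adjusted deaths for survival) and expected $E_i$, the statistic at spatial
scale $\lambda$ is

$$C(\lambda) = \sum_{i}\sum_{j} e^{-d_{ij}/\lambda}
\Big(\tfrac{O_i}{O_+} - \tfrac{E_i}{E_+}\Big)
\Big(\tfrac{O_j}{O_+} - \tfrac{E_j}{E_+}\Big),$$

maximised (as minimum p) over a grid of $\lambda$ and calibrated by
multinomial Monte-Carlo replicates of $O_+$ events with probabilities
$E/E_+$. Two independent replicate sets are drawn: set A converts each
$C(\lambda)$ to a per-scale p-value, set B calibrates the minimum-p
statistic itself, avoiding double use of the same replicates. Defaults:
10 log-spaced $\lambda$ spanning the 1st-99th percentile of pairwise
centroid distances, $n_{rep} = 999$ per set, boundary-corrected p-value
$(1 + \#\{\text{replicates} \le \text{obs}\})/(1 + n_{rep})$. Adjusted
p-values classify as strong ($< 0.01$), moderate ($[0.01, 0.05)$), weak
($[0.05, 0.10)$) or no evidence ($\ge 0.10$); because the test is
Monte-Carlo, `stable_classify()` repeats it six times with distinct seeds
and, when runs disagree, reports the more conservative (less significant)
category. The survival input uses posterior-median parameters
(point-estimate adjusted deaths); per-draw adjusted deaths are reserved for
stratum aggregation, which is defined per-iteration.

## Aggregation and map products

`group_estimates()` aggregates at the draw level: for each stored draw the
modelled observed value of every area ($\theta_i^{(t)} e_i$, or the
adjusted deaths under draw-$t$ parameters) is summed within a stratum
(socioeconomic quintile from ranking a disadvantage score; rurality with
remote categories merged upstream) and divided by the stratum's summed
expected value — for survival, the fixed RER = 1 totals at
posterior-median parameters. The stratum chain's median and 2.5/97.5
percentiles give the estimate and interval. All percentile operations in
the package, here and in `summarize_sir()`/`summarize_rer()`, use type-7
linear interpolation between order statistics.

`categorize_for_map()` applies the atlas's five diverging classes with cut
points $1/1.3, 1/1.1, 1.1, 1.3$ — more than 30% below, 10-30% below, within
10%, 10-30% above, more than 30% above the regional average. The cut-offs
alone leave open which side each boundary belongs to; here the central
class is closed on both sides ($[1/1.1, 1.1]$) and the outer cut-offs
belong to the inner class, a symmetric, tested convention.
`export_products()` writes the GeoJSON choropleth (categories and
intervals as properties, no colour styling), the ranked caterpillar table,
and per-stratum box-plot summaries.

## The synthetic-data generator

`make_geography()` builds a unit-square lattice plus detached island
polygons (queen contiguity joins corner neighbours, islands start as
isolates, mimicking a coastal mosaic at up to the scale of ~500 areas with
18 islands). `simulate_populations_and_lifetable()` produces 18 five-year
age groups (0-4 … 85+) by sex and year with log-normal area-size variation
and Gompertz-like all-cause mortality (doubling roughly every 7 years of
age, males ~50% above females) — order-of-magnitude realism, not a
calibration to any particular registry. `simulate_incidence()` draws the
spatial field by Gibbs sampling of the intrinsic CAR conditionals (200
sweeps from zero, centred); because the intrinsic field is improper, its
"marginal scale" is defined empirically by rescaling to the requested SD.
`simulate_survival_records()` draws diagnosis dates over the accrual span,
ages from the population pyramid, and event times piecewise-exponentially
at yearly resolution with total hazard = life-table background + planted
excess $\exp(\alpha_j + \beta_k + u_i + v_i)$ — exactly the fitting model's
assumption, deliberately, so that parameter-recovery tests isolate the
sampler rather than model misspecification. Configurable fractions of
records carry death-certificate-only, autopsy-only or age-90+ flags to
exercise the exclusion rules.

What passing tests on these data do **not** show: robustness to real
registries' geocoding errors, late registrations, life tables that do not
match the background population, or excess hazards that vary continuously
rather than by follow-up year.

## Data preparation conventions

Survival exclusions drop records aged 90+ at diagnosis, death-certificate-
or autopsy-only diagnoses, and zero-or-negative survival times; anyone
contributing at-risk time inside the study window within five years of
diagnosis is kept, with the follow-up clock always starting at diagnosis,
and survivors censored at the window end. Person-time is split exactly at
the annual anniversaries of diagnosis and the window boundaries,
day-precision, with person-years = days/365.25. Expected background deaths
use the life-table rate at the attained age and calendar year of each
segment's midpoint — an Ederer-II-style approximation; day-level exactness
would be spurious given annual life tables. Broad age groups default to
<60, 60-69, 70-79, 80-89; there is no single canonical choice, so both the
cut points and the background-death estimator are configuration.

## Numerical choices and validation

* Degenerate inputs: empty polygon sets, duplicate labels, asymmetric GAL
  files, negative $d^*$, zero expected counts, and isolate-containing
  graphs passed to the fitters are all rejected with informative errors.
  Zero-variance chains give Geweke $z = 0$, $p = 1$.
* Tie-breaks: an isolate equidistant from two candidates links to the area
  earlier in id order.
* The samplers are validated against independent grid quadrature of the
  exact posteriors: for the incidence model on a 3-area toy, the posterior
  mean of every $\theta_i$ from a 200,000-sweep chain agrees with a
  marginalised 3-D + 2-D quadrature within 3 Monte-Carlo standard errors;
  parameter recovery on a 10×10 lattice (expected counts 50,
  $\sigma_u = 0.3$, $\sigma_v = 0.1$) achieves 90-98% credible-interval
  coverage and rank correlation with truth above 0.7; null simulations
  keep false-positive areas below 8% and the clustering test classifies
  "none" in at least 9 of 10 seeded repeats; the excess-mortality model on
  an 8×8 lattice with 20,000 simulated cases recovers a planted doubled
  hazard with an interval excluding 1. These problem sizes are the
  package's chosen validation conditions and run in seconds to minutes.
* A known identifiability caveat: in toys with only 2-3 areas the mean of
  $\exp(u_i + v_i)$ is not a stable functional — the gamma hyperpriors give
  the effects heavy tails and the common level of $v$ trades off against
  the vague intercept — so the survival sampler's quadrature cross-check
  compares posterior means on the log scale. At realistic area counts the
  collective shrinkage of $v$ removes the issue.

## Limitations

No covariate-adjusted models (rurality and socioeconomic status are
aggregation strata, not model terms), single-chain inference by design, no
local cluster detection, no cartographic styling, planar coordinates only
(pre-project real geographies), and no period/hybrid survival estimation.
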