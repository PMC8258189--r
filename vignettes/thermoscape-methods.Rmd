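---
title: "Methods: thermal performance, SDM ensembles and dispersal scenarios on river networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal performance, SDM ensembles and dispersal scenarios on river networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscape)
```

## The problem

Correlative species distribution models (SDMs) project where a species can
occur under a changed climate, but say nothing about how well it will do
there, and nothing about whether it can get there. `thermoscape` couples
three ingredients at the scale of river catchments:

1. **life-stage thermal performance curves (TPCs)** that translate monthly
   water temperature into a survivorship rate for adults, juveniles and
   eggs;
2. an **ensemble SDM** over catchment-level covariates, validated by
   repeated split-sampling and reduced to a presence/absence map through a
   sensitivity–specificity balanced threshold;
3. **dispersal scenarios** resolved on the dendritic river network, where a
   future presence only counts if it is connected — possibly through
   unsuitable catchments, but not through dams — to a currently occupied
   catchment.

Because the package is developed and tested against a seeded synthetic
world with a *known* thermal niche, every stage can be checked for
parameter recovery without any external data.

## Thermal performance curves

Each life stage is described by three temperatures obtained from laboratory
studies: the critical minimum (CTmin) and maximum (CTmax) for survival and
the optimum Topt, taken as the upper limit of the reported optimum range.
When several studies report a trait, `finalize_traits()` uses the
*narrowest* supported window by default: the maximum of the observed CTmin,
the minimum of the observed CTmax, and the maximum reported optimum. The
sentence structure of published trait syntheses also admits the opposite
reading (widest window, min-CTmin / max-CTmax); that alternative is
available as `rule = "wide"` but is not the default, because the narrow
window is the only one every contributing study is consistent with.

The curve itself is the Deutsch-type survivorship form. With
$\sigma_p = (T_{opt} - CT_{min})/4$,

$$
P(T) \;=\;
\begin{cases}
\exp\!\left[-\left(\dfrac{T - T_{opt}}{2\sigma_p}\right)^{2}\right]
  & CT_{min} \le T \le T_{opt},\\[2ex]
1 - \left(\dfrac{T - T_{opt}}{T_{opt} - CT_{max}}\right)^{2}
  & T_{opt} < T \le CT_{max},\\[2ex]
0 & \text{otherwise.}
\end{cases}
$$

Numerical notes:

* Both branches equal 1 at $T_{opt}$, so the curve is continuous at the
  mode; the fall branch reaches exactly 0 at $CT_{max}$.
* The raw Gaussian branch does not vanish at $CT_{min}$ (it equals
  $e^{-4} \approx 0.018$ there). Performance is therefore **clamped to 0
  outside $[CT_{min}, CT_{max}]$** by default, honouring the boundedness of
  survivorship at the critical limits; `clamp = FALSE` exposes the raw
  branches for sensitivity analysis.
* The familiar "slow rise, rapid drop" skew should be read asymptotically,
  not as a pointwise guarantee: for this functional form,
  $P(T_{opt}-d) \ge P(T_{opt}+d)$ holds for *every* admissible $d$ exactly
  when the rise width is at least twice the fall width
  ($T_{opt}-CT_{min} \ge 2\,(CT_{max}-T_{opt})$, via
  $e^{-x} \ge 1-x$). Mildly skewed curves can locally fall slower than they
  rise, and the property suite tests the condition under which the
  guarantee is real.

```{r tpc-example, fig.width = 5, fig.height = 3.5}
adult <- tpc(0, 16, 25, life_stage = "adult")
plot(adult, main = "Adult survivorship TPC")
tpc_evaluate(adult, c(8, 16, 20, 25))
```

## The synthetic world

`synthetic_world()` generates, from one root seed, every input the analysis
consumes. It emulates the statistical structure the pipeline assumes — not
geographic realism.

| component | design | default |
|---|---|---|
| network | one random-attachment tree per region; regions never connected | 500 catchments, 4 regions |
| latitudes | disjoint per-region bands, both hemispheres | 30–65°N, 30–65°S, 25–55°N, 25–55°S |
| catchment area | 3000 km² + lognormal excess (all pass the ingestion floor) | ≥ 3000 km² |
| monthly water temperature | lat-linear annual mean + seasonal cosine, peak July (NH) / January (SH) + iid noise | 27 − 0.35·&#124;lat&#124; °C mean, ±8 °C season, 0.5 °C noise |
| future period | baseline + uniform warming offset (new noise draw) | +2.2 °C |
| covariates | altitude, winter discharge, land-cover fractions correlated with the thermal regime; temperature statistics derived per period | 5 static + 4 derived |
| dams | uniform sample of `round(fraction × edges)` edges | 20 % of edges |
| trait observations | Gaussian noise around the true stage triples | 5 obs/trait, sd 0.5 °C |
| occurrences | logistic link on annual-mean adult survivorship, centred to the target prevalence | prevalence 0.3, steepness 120 |

The warming offset of 2.2 °C matches the global mean warming attached to
the RCP6.0 concentration pathway that the 2050s projections represent. The
seasonal phase shift of six months between hemispheres is what makes the
hemisphere-aware season and spawning logic testable.

The presence link deserves a note. Occupancy is Bernoulli with probability
$\mathrm{logit}^{-1}\!\big(b\,(\bar P_{adult} - m)\big)$, where
$\bar P_{adult}$ is the annual-mean adult survivorship under the *true*
TPC and $m$ is solved (by `uniroot`) so that the expected prevalence hits
its target. The steepness $b = 120$ makes occupancy a near-threshold rule
with a stochastic transition zone of roughly 0.03 survivorship units. A
shallow link (say $b = 10$) yields worlds in which even the Bayes-optimal
classifier barely reaches AUC 0.66 — label noise, not model quality, would
then dominate every validation statistic, and parameter recovery would be
unattainable *by construction*. The steep link instead represents a species
whose range boundary genuinely tracks its thermal niche, which is the
premise the whole analysis rests on.

What the generator does **not** emulate: spatial autocorrelation of
residual noise, sampling bias in occurrences, real basin topology and area
distributions, non-thermal range limits (discharge extremes, biotic
interactions), and observation error in the occurrence labels themselves.
Passing tests on this world therefore demonstrate that the machinery
recovers a recoverable signal — not that any real data set carries one.

## The ensemble SDM

**Variable selection** applies three screens: univariate AUC ≥ 0.65,
pairwise absolute Pearson correlation < 0.7 among retained variables
(greedy, in descending univariate-AUC order), and a whitelist for variables
supported by prior studies — whitelisted variables ignore the AUC floor but
never the correlation cap. Univariate strength is scored by a univariate
binomial GAM smooth rather than by the raw variable, because a species with
an interior thermal optimum produces a hump-shaped response that raw-score
AUC cannot see.

**Learners.** Four families stand behind a pluggable fit/predict-probability
contract: elastic-net logistic regression (`glmnet`), random forest
(`ranger`), gradient-boosted trees (`xgboost`) and a spline-based binomial
additive model (`mgcv`). The consensus mechanics — not any particular
learner — are the point, and the contract accepts user-supplied families.

**Tuning** is random search (default budget 30 draws per family,
config-scalable upward; finite spaces are capped with a warning): each draw
is scored by mean AUC over 5 stratified folds of a stratified 80 %
partition, the winner is refit on the full 80 % and reported against the
withheld 20 %.

**Validation** repeats a stratified 80/20 split (default 100 times; the
package's own recovery runs use 20 to stay desk-scale): per split each
learner is refit on the calibration part, its threshold is selected *on
calibration predictions only*, and AUC, sensitivity, specificity and
TSS (= sensitivity + specificity − 1) are computed on the validation part.
The consensus — the arithmetic mean of member probabilities — is validated
identically. Whether thresholds should be refit per split is not uniquely
determined by common practice; refitting is the only choice that keeps the
validation part untouched, so it is adopted.

**Consensus and threshold.** Only learners with mean validation AUC > 0.85
enter the consensus (on the default synthetic world the elastic-net member
typically falls below the cutoff and is excluded — a linear logistic model
cannot express an interior optimum). Averaging precedes thresholding: the
final threshold is selected on full-data consensus probabilities, and a
catchment is predicted present when its probability is **at or above** the
threshold.

**Threshold selection** scans the midpoints of consecutive sorted unique
scores plus one candidate below the minimum and one above the maximum
(offset by half the smallest score gap, or 0.5 for degenerate
constant-score inputs), minimizing |sensitivity − specificity|; ties break
by larger TSS, then by the larger threshold (the more conservative range
map).

## Dispersal scenarios

* `no_dispersal` — the future range *is* the baseline range (which
  catchments are affected if nothing moves);
* `free_dispersal` — predicted future presences that are connected through
  the river network to a baseline presence; a catchment that is itself a
  baseline presence survives via the zero-length path;
* `restricted_dispersal` — the same with dammed edges removed.

Three deliberate choices: paths may traverse unsuitable catchments (only
endpoint status matters); dams block both directions (passability is not
distinguished by direction); and regions are never connected to each other,
so marine or out-of-basin routes do not exist in the model. Range change is
reported as `round(100 × (n_scenario − n_baseline)/n_baseline)`, rounding
half away from zero.

## Performance assessment

For every scenario presence set, each stage's TPC is evaluated at the
catchment's monthly water temperature of the matching period (baseline
scenario → baseline temperatures, dispersal scenarios → future
temperatures). Egg records exist only within the spawning season — October
to February in the northern hemisphere, April to August in the southern,
treated as an unordered month set within one climatological year.

Hemispheres are assessed separately (centroid latitude ≥ 0 is "north"),
and all seasonal, annual and latitudinal summaries weight every
catchment-month cell equally; with complete monthly coverage this makes
the annual mean equal the mean of the four seasonal means, a balance the
tests exploit. Southern-hemisphere rows keep northern season names with the
locally experienced season alongside, so the two hemispheres stay
comparable row by row. The latitudinal profile bins per-catchment annual
means into fixed-width bins (default 1°), omitting empty bins.

The suitability–performance correlation is the Pearson coefficient between
the baseline consensus probability and the per-catchment performance
(annual mean for adults and juveniles, spawning-season mean for eggs) over
*baseline-present* catchments, with the standard t-based two-sided p-value
and no multiple-testing adjustment (one test per stage). Restricting to
occupied catchments matches the question being asked — does suitability
track performance where the species actually lives; an all-catchment
variant can be had by passing a wider probability vector.

## Reproducibility and problem sizes

Every stochastic stage consumes a seed derived from one root seed through a
fixed counter scheme (`derive_seed()`), so `run_pipeline()` is reproducible
byte-for-byte, and stages can be re-run in isolation. Stage boundaries are
logged with record counts after every filter, and a manifest records the
config hash, seed and package version.

The package's own recovery runs use the default world (500 catchments,
4 regions), a tuning budget of 30 draws and 20 validation splits — sizes
chosen so a complete fit, scenario resolution and assessment run in well
under a minute on one core while leaving the validation distributions
stable enough to read. On that design the consensus reaches a mean
validation AUC of about 0.91–0.96 across seeds, recovers the truth-optimal
range with Jaccard ≥ 0.7, and reproduces the qualitative summer story: a
northern-hemisphere summer survivorship drop when the current range is held
fixed under warming, mitigated when dispersal through the network is
allowed, and partially re-lost when dams cut the paths.

## Known limitations

* TPCs are static: no acclimation, hardening, exposure-duration effects or
  oxygen limitation; laboratory-derived limits need not match field
  mortality.
* The trait max/min finalization collapses methodological differences
  (incipient-lethal vs critical-thermal protocols) without weighting.
* The SDM learners are a four-family stand-in for larger operational
  stacks; no presence-only learner (MAXENT-style) is included, and all
  non-presence catchments are treated as absences.
* Dispersal is binary connectivity — no distance limits, spread kinetics or
  partial dam passability.
* The synthetic world's independence assumptions (iid noise, independent
  Bernoulli occupancy) make recovery easier than on spatially
  autocorrelated real data.
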