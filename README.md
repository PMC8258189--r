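# thermoscape

Climate-change range projections tell you *where* a coldwater fish could
persist; they do not tell you *how well* it would do there, nor whether it
can reach the place at all. `thermoscape` couples the three pieces needed
to ask all of that at once, at the river-catchment scale:

* **Life-stage thermal performance curves (TPCs).** Laboratory thermal
  traits — critical minimum (CTmin), optimum (Topt) and critical maximum
  (CTmax) temperature — are finalized per life stage (adult, juvenile, egg)
  and turned into a Deutsch-type survivorship curve: a Gaussian rise below
  the optimum with scale σ = (Topt − CTmin)/4, a quadratic decline above
  it, and zero outside [CTmin, CTmax].
* **An ensemble species distribution model (SDM).** Covariates are screened
  by univariate AUC (≥ 0.65), collinearity (|r| < 0.7) and a literature
  whitelist; four tunable learner families (elastic-net logistic, random
  forest, gradient boosting, binomial GAM) are tuned by random search with
  5-fold cross-validation on a stratified 80 % partition and validated
  over repeated 80/20 splits (AUC, sensitivity, specificity,
  TSS = sensitivity + specificity − 1). Learners with mean validation
  AUC > 0.85 are averaged into a consensus probability, binarized at the
  threshold minimizing |sensitivity − specificity|.
* **Dispersal scenarios on the river network.** Future presences are kept
  under *no dispersal* (range frozen at baseline), *free dispersal*
  (predicted presences connected through the dendritic network to a
  baseline presence) and *restricted dispersal* (the same, with dammed
  edges removed). Monthly, seasonal, annual and spawning-season
  survivorship summaries, latitudinal profiles, and the
  suitability–performance correlation complete the assessment.

A seeded synthetic-world generator (dendritic catchment networks, monthly
water temperatures for a baseline and a +2.2 °C future, correlated
covariates, dams, replicated trait observations, occurrences drawn from a
known thermal niche) makes every stage testable end to end with no
external data, including parameter recovery against the known truth.

Audience: ecologists and methodologists working on freshwater climate
impact assessment who want the SDM × traits × connectivity mechanics as a
tested, reusable library rather than a one-off script stack.

## Worked example

```r
library(thermoscape)

# A 500-catchment world with a known niche, warmed by +2.2 °C
w <- synthetic_world(seed = 1)
w$network
#> Catchment network: 500 catchments, 496 edges, 4 regions
#>   latitude span: -64.9 to 65.0 (NH 250 / SH 250)

# Finalize traits from the noisy laboratory observations
fin <- finalize_all_traits(w$traits)
fin
#>              species life_stage  ct_min t_opt ct_max
#> 1 synthetic_salmonid      adult  0.6472 16.20   24.4
#> 2 synthetic_salmonid   juvenile -0.0319 18.12   25.7
#> 3 synthetic_salmonid        egg  0.5095  8.36   12.4
tpcs <- tpc_from_traits(fin)

# Fit the consensus SDM on baseline features
ids <- w$network$catchments$catchment_id
fb  <- feature_table(w$env, "baseline")
fb  <- fb[match(ids, fb$catchment_id), ]
dat <- cbind(fb[-1], presence = as.integer(ids %in% w$occurrences))
fit <- consensus_sdm(presence ~ ., dat, tune_budget = 30, n_splits = 20,
                     seed = derive_seed(1, 50))
fit
#> Consensus SDM
#>   variables: water_temp_annual_mean, mean_winter_discharge
#>   learners:  elnet (excluded), rf, gbm, gam
#>   consensus mean validation AUC: 0.913 over 20 splits
#>   binarization threshold: 0.483

# Project the future range and resolve the dispersal scenarios
ff   <- feature_table(w$env, "future")
ff   <- ff[match(ids, ff$catchment_id), ]
scen <- dispersal_scenarios(predict_range(fit, ff), w$occurrences,
                            w$network, w$dams)
scen$free_dispersal
#> Scenario 'free_dispersal': 187 presences

# Seasonal survivorship per scenario, northern hemisphere
surface <- assemble_surface(c(list(baseline = w$occurrences), scen),
                            w$env, tpcs, w$network)
ss <- seasonal_summary(surface, hemisphere = "NH")
subset(ss, life_stage == "adult" & timeframe == "summer",
       c(scenario, mean_rate))
#>                scenario mean_rate
#>                baseline 0.5835056
#>            no_dispersal 0.2345946
#>          free_dispersal 0.5658161
#>    restricted_dispersal 0.5424418
```

The summer story is the headline: holding the range fixed under warming
(`no_dispersal`) cuts mean northern-hemisphere summer survivorship from
0.58 to 0.23, free movement through the network recovers most of it
(0.57), and dams claw part of that back (0.54). The linear elastic-net
learner is excluded from the consensus (mean validation AUC below 0.85) —
a species with an interior thermal optimum defeats a linear logistic
response, which is exactly why the ensemble exists.

`run_pipeline(default_config(seed = 1), "out/")` runs all five stages and
writes every table (network, temperatures, traits, validation report,
consensus probabilities, scenario ranges, performance summaries,
correlations) as plain CSV/JSON plus a manifest; identical config and seed
reproduce byte-identical outputs.

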