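# wetrisk

Machine-learning prediction of antibiotic removal in wetlands, and
regional antibiotic risk assessment built on top of it.

Veterinary antibiotics emitted by livestock farming reach surface waters,
where wetlands — natural marshes, reservoirs, and constructed treatment
systems — remove part of the load. `wetrisk` implements the full analysis
chain for quantifying and managing the residual risk:

1. **Removal prediction.** The antibiotic removal efficiency (ARE, %) of a
   wetland trial, defined from pooled influent/effluent concentrations as
   `ARE = 100 (1 - Σc_eff / Σc_inf)`, is predicted from 19 trial features
   (water chemistry, configuration, hydraulics, construction). Five learner
   families (XGBoost, random forest, KNN, SVR, a KNN-boost hybrid) are tuned
   by 5-fold cross-validation under grid / random / Bayesian search; the best
   candidate by held-out R² is refit as a 100-member bootstrap ensemble
   giving per-prediction standard deviations and 95% intervals. Missing
   cells are filled by iterative random-forest (missForest-style)
   imputation.
2. **Mass balance and cask-effect risk.** County emissions are allocated to
   wetlands (area-proportional "no management", or multistage "improved
   management" routing everything through constructed wetlands first), giving
   the surplus `AS = AI - ΣAR` with `AR = AI × ARE`. Each wetland's surplus
   concentration `c_surp = c (1 - ARE)` yields the cask-effect risk quotient
   `RQ = c_surp / (n × PNEC_min)` — aggregate risk governed by the most
   sensitive antibiotic in the emission inventory (minimum algal PNEC,
   3 ng/L by default). Counties holding a high-risk (RQ > 1) natural-class
   wetland accumulate into the high-risk county area (HRA, km²).
3. **Policy scenarios to 2035.** Eighteen combinations of management
   (NM/IM), wetland restoration (none / proportional / targeted at
   high-risk counties, 180 km²/yr) and antibiotic abatement (20/40/60%,
   phased in by a farm-participation ramp reaching 50% in 2025 and 100% in
   2035) are projected yearly, with uncertainty bands from propagating
   bootstrap members through the whole chain, plus a control-variable
   contribution analysis per measure.
4. **Interpretation.** Exact double-precision TreeSHAP attributions (local
   accuracy to ~1e-13) with category-level shares, cross-checked by
   permutation importance.

A synthetic-data module generates experiment tables, regional states and
antibiotic inventories with the statistical structure the analysis assumes,
so everything above is testable end to end without external data.

## Worked example

```r
library(wetrisk)

# a literature-style experiment table: 337 trials, 19 features + ARE target
experiments <- gen_experiments(n = 337, seed = 1, missing_rate = 0)

# impute -> split -> tune 5 families -> select -> bootstrap ensemble
m <- are_model(are ~ ., experiments, B = 100, seed = 1)
m
#> Wetland antibiotic removal efficiency model
#>   selected: xgboost (grid search) from 5 candidate(s)
#>   train R2 0.873 | test R2 0.733 | test RMSE 12.56 | gap 0.140
#>   bootstrap ensemble: B = 100
```

The selected gradient-boosting model explains 73% of held-out variance with
a train-test gap well under the 0.15 overfitting flag. Predictions come
with bootstrap uncertainty (mean, sd, 95% interval, all in ARE %):

```r
trials <- gen_independent_validation(12, seed = 42)
predict(m, trials[1:3, ])
#>   mean  sd  lwr  upr
#> 1 62.3 4.3 55.0 71.8
#> 2 35.5 4.6 26.0 43.9
#> 3 65.0 4.7 56.2 72.7
```

Regional risk under the two management modes — multistage treatment lifts
total removal from 72.8% to 81.4% of the 204 t/yr emission and shrinks the
high-risk county area by a fifth:

```r
region <- gen_region(40, seed = 3)
assess_region(region, "NM", m)
#> Risk assessment (NM): emission 204.18 t, removal 148.58 t (72.8%), surplus 55.60 t
#>   high-risk county area: 42010 km2 (17 of 40 counties)
assess_region(region, "IM", m)
#> Risk assessment (IM): emission 204.18 t, removal 166.13 t (81.4%), surplus 38.05 t
#>   high-risk county area: 33564 km2 (13 of 40 counties)
```

Projecting the strongest policy mix (improved management, targeted
restoration, 60% abatement) more than halves the HRA by 2035; the band is
the 2.5/97.5 percentile across bootstrap-member chains:

```r
best <- project_scenario(list(management = "IM", restoration = "WR3",
                              abatement = 0.6), region, m, members = 10)
best[c(1, 8, 15), ]
#>    year   hra   lwr   upr hra_mean_are
#> 1  2021 33564 29584 33564        33564
#> 8  2028 21921 17050 24864        20858
#> 15 2035 14753  7971 18581        14753
```

Finally, additive attributions identify what drives predicted removal —
influent antibiotic concentration dominates, and water-quality properties
carry half of the total attribution mass:

```r
at <- attribute(m)   # exact TreeSHAP on the held-out partition
sort(at$mean_abs, decreasing = TRUE)[1:5]
#> antibiotic_conc modified_substrate planting_density structural_type tetracycline_pct
#>           13.03               6.11             4.63            3.40             3.05
category_shares(at)
#> water_quality artificial_config hydraulic_temp construction
#>          50.2              24.0           17.6          8.1
```

`run_pipeline(default_config(seed = 1))` executes the whole chain
(generate → fit → assess NM/IM → 18 scenarios → interpret) and writes CSV
artifacts plus a machine-readable `summary.json`.

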