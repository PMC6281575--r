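# arealscan

Spatial cluster detection and ecological regression for areal screening
prevalence data.

`arealscan` is for epidemiologists and biostatisticians analysing the
geographic distribution of cases detected by a mass screening programme,
aggregated to administrative regions (municipalities). It answers three
questions about a set of region-level case counts: Is there a localised
cluster of elevated prevalence anywhere? Is there a general tendency of
spatial clustering at any scale? Is prevalence associated with regional
indicators (distance to a point source, altitude, socio-economic
measures)? It also quantifies how much the answers could move if
screen-positive participants who skipped confirmatory testing had hidden
cases among them.

## Methods at a glance

With `o_i` observed and `e_i = Σ_k pop_ik pr_k` indirectly standardised
expected cases (sex × 5-year age strata), the package assumes
`o_i ~ Poisson(r_i e_i)` and tests homogeneous risk `r_i ≡ 1` by:

- **Flexibly shaped spatial scan** — maximises the one-sided Poisson log
  likelihood ratio
  `LLR(Z) = o_Z log(o_Z/e_Z) + (O−o_Z) log((O−o_Z)/(E−e_Z))`
  over all connected windows of at most `k_max` regions (each seed plus
  its nearest neighbours), with a conditional multinomial Monte Carlo
  p-value; a circular scan is included as the classical baseline.
- **Tango's C-index / MEET** — the quadratic-form clustering statistic
  `C(λ) = Σ_ij exp(−4(d_ij/λ)²)(o_i/O − e_i/O)(o_j/O − e_j/O)` profiled
  over a grid of scales λ, with the maximised excess events test
  adjustment for the scale search.
- **Offset Poisson regression** — univariate `log r_i = β0 + β1 x_i`
  with offset `log e_i`, Wald tests, quartile categories with a
  score-based trend test, residual deviance and AIC.
- **Sensitivity imputation** — hypothetical diagnoses drawn
  `Binomial(u_ik, q_k)` among undiagnosed screen-positives, the whole
  analysis re-run per draw, p-value distributions reported.
- **Synthetic studies** — `simulate_study()` generates full input bundles
  (59 regions, ~295k examinees, ~115 cases by default, optional embedded
  elevated-risk clusters) for calibration and power work.

## Worked example

```r
library(arealscan)

cfg <- sim_config(clusters = list(list(rule = "contiguous", rr = 3,
                                       center = 20, size = 5)))
study <- simulate_study(cfg, seed = 8)
study
#> synthetic_study (seed 8): 59 regions, 295,032 examinees, 141 cases
#>   screen-positives 2251, undiagnosed pool 205, clusters: 1

et <- expected_counts(study$strata)
pos <- match(study$map$region_id, et$region_id)
o <- et$observed[pos]; e <- et$expected[pos]

scan_flexible(o, e, study$map, k_max = 10, R = 999, seed = 101)
#> flexible spatial scan (k_max = 10, 16653 windows, R = 999)
#> most likely cluster: 4 regions [R13, R20, R21, R29]
#>   observed 45, expected 24.46, relative risk 1.840
#>   LLR 8.8194, Monte Carlo p = 0.008
#> 5 non-overlapping secondary cluster(s) reported
study$truth$clusters[[1]]$members
#> [1] "R19" "R20" "R21" "R28" "R29"

meet(o, e, study$map$dist, R = 999, seed = 102)
#> MEET: 20 scales from 5.0 to 100.0 km, R = 999
#>   smallest unadjusted p at lambda = 5.0 km (p = 0.004)
#>   scale-adjusted p = 0.009

fit_poisson(o, e, study$covariates$dist_source_km)
#> offset Poisson regression (continuous form), n = 59 regions
#>   (Intercept)    RR    0.882  (0.529, 1.47)  Wald p = 0.629
#>   x              RR        1  (0.996, 1.01)  Wald p = 0.607
#>   residual deviance 77.326, AIC 197.26 (null: 77.592, 195.53)
```

The scan localises the embedded relative-risk-3 cluster (3 of its 4
reported regions are true members) with Monte Carlo p = 0.008; MEET
agrees that residuals cluster spatially (adjusted p = 0.009); the
distance covariate, which was not linked to risk in this simulation, is
null as expected (Wald p = 0.61). On a homogeneous-risk bundle all three
p-values are approximately uniform — the test suite checks this
calibration over 300 studies.

The same analyses run end-to-end from delimited files via
`run_pipeline()` (see `?run_pipeline` for the YAML/list configuration),
writing `expected.csv`, `scan.json`, `meet.csv`/`meet.json`, regression
tables, sensitivity outputs and a reproducibility manifest.

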