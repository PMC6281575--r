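---
title: "Detecting spatial clusters and ecological gradients in areal screening prevalence data"
author: "arealscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatial clusters and ecological gradients in areal screening prevalence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealscan)
```

## The problem

A mass screening programme examines a large cohort across a set of
administrative regions and detects a modest number of cases of a rare
disease. The scientific question is geographic: is prevalence spatially
homogeneous once the sex and age structure of the examinees is accounted
for, or are there regions — or broader spatial scales — with elevated risk,
possibly attributable to an environmental point source? `arealscan`
implements the full analysis chain for this design: indirect
standardisation, cluster detection by spatial scan statistics, a general
clustering test across spatial scales, univariate ecological Poisson
regression, and a simulation-based sensitivity analysis for the two-phase
structure of screening programmes (screen-positives who never complete
confirmatory testing).

The motivating scale, which the synthetic-data generator reproduces by
default, is a prefecture-sized study: 59 municipalities in a 165 × 132 km
extent, roughly 295,000 examinees in ten sex-by-age strata, on the order of
115 detected cases, about 2,250 screen-positives of whom roughly 91% take
up confirmatory testing, leaving a pool of about 195 undiagnosed positives.

## Model and null hypothesis

Counts are modelled at the region level. With `pop_ik` examinees in region
`i` and stratum `k` (sex × 5-year age band: 0–4, 5–9, 10–14, 15–19, 20+),
the prefecture-wide marginal rates `pr_k` give the indirectly standardised
expectation and the standardised prevalence ratio

    e_i = sum_k pop_ik * pr_k,        spr_i = o_i / e_i.

Cases are assumed Poisson, `o_i ~ Poisson(r_i e_i)`, and the null
hypothesis of every test in the package is geographically homogeneous risk,
`r_i = 1` for all regions. When the rates are computed internally from the
same table, `sum(e_i) = sum(o_i)` holds exactly; `expected_counts()`
verifies this to relative tolerance 1e-10. A region with `e_i = 0` gets a
flagged, missing `spr` rather than a silent 0/0 or infinity.

## Flexibly shaped spatial scan

`scan_flexible()` searches for the connected set of regions (a *window*)
that maximises the one-sided Poisson log likelihood ratio

    LLR(Z) = o_Z log(o_Z/e_Z) + (O - o_Z) log((O - o_Z)/(E - e_Z))

if the rate inside exceeds the rate outside, and 0 otherwise, with
`0·log 0 := 0`. Windows are generated from every seed region: all connected
subsets of at most `k_max` members drawn from the seed plus its
`k_max - 1` nearest neighbours by Euclidean distance, deduplicated across
seeds. This nearest-neighbour restriction is what bounds the otherwise
exponential enumeration; with `k_max` at its default of 15 the window count
on a 59-region contiguity graph is in the hundreds of thousands and
enumeration takes tens of seconds, so the enumeration (`flex_windows()`)
is exposed separately and reusable across case vectors.
`scan_circular()` provides the classical distance-based baseline whose
windows are each seed plus its `j` nearest regions.

Inference is by Monte Carlo: conditional on the case total `O`, replicate
case vectors are multinomial with probabilities `e_i / E` — equivalent to
independent Poissons conditioned on their total — and the p-value of the
most likely cluster is `(1 + #{replicate max LLR >= observed max LLR}) /
(R + 1)` with `R = 999` by default. Ties in LLR are broken toward the
smaller window, then lexicographically by member ids, so output is
deterministic given `(seed, R)`. Secondary clusters are reported
non-overlapping in decreasing LLR order, each ranked against the same
replicate maxima, which is deliberately conservative. The one-sided
"high-risk windows only" form matches the elevated-risk question; the
risk-threshold-restricted scan variant is intentionally not implemented.

## General clustering: the C-index and MEET

Scan statistics target one anomalous window; Tango's C-index asks instead
whether prevalence residuals are spatially autocorrelated at a scale
`lambda`:

    C(lambda) = sum_ij exp(-4 (d_ij / lambda)^2) (o_i/O - e_i/O)(o_j/O - e_j/O).

The Gaussian kernel is positive semi-definite, so `C >= 0`; the weight
falls to about 0.018 at distance `lambda`, making `lambda` an interpretable
"similarity range" in km. Because the best scale is unknown, `meet()`
evaluates a grid (default 5–100 km in 5 km steps, chosen to span from the
typical nearest-neighbour spacing to about half the default map diagonal)
and adjusts for the scale search: one multinomial null draw per replicate
serves the whole grid, each replicate's C is rank-ranked against all
replicates per scale, and the null distribution of the minimum
per-replicate p across scales calibrates the observed minimum p. No
chi-square approximation is offered: with on the order of 100 cases over
59 units the asymptotics are unreliable, and Monte Carlo is cheap here.

Two numerical caveats are documented rather than hidden. First, a grid
scale beyond twice the map diameter makes all weights near 1 and the test
degenerate — `meet()` warns. Second, the C statistic and the observed
profile are exactly invariant under a relabelling of regions, but the
Monte Carlo p-values are invariant only in distribution, because
multinomial generation is order-dependent; tests assert the former exactly
and the latter statistically.

## Ecological regression

`fit_poisson()` fits `o_i ~ Poisson(r_i e_i)` with `log r_i = b0 + b1 x_i`
by iteratively reweighted least squares (`stats::glm`, convergence
tightened to 1e-12), using `log(e_i)` as the offset so `exp(b)` are rate
ratios against the standardised expectation. Wald p-values use the normal
approximation and 95% intervals are symmetric on the log scale. The
quartile form cuts the covariate at its empirical 25/50/75 percentiles
(linear interpolation on order statistics; ties fall to the lower
category; empty categories are rejected rather than silently merged), with
Q1 as reference, and the trend test refits with integer scores 1–4 — the
standard epidemiological "p for trend". One model per covariate, exactly
as univariate ecological tables are reported; AIC uses the full Poisson
log-likelihood, and the identity `AIC_null - AIC_alt =
dev_null - dev_alt - 2` for one added parameter is checked in the tests. A
constant covariate degrades to the null model with a warning rather than
erroring, matching the offset identity `exp(b0) = O / sum(e) = 1` under
internal standardisation.

## Sensitivity analysis for undiagnosed screen-positives

Screen-positives who decline confirmatory testing could hide cases. The
sensitivity analysis assumes the diagnosis rate among positives depends on
sex and age only: `q_k = diagnosed_k / tested_k` from the confirmatory
phase (`diagnosis_rates()`). Each run of `run_sensitivity()` draws
`Binomial(u_ik, q_k)` hypothetical cases across the undiagnosed pool,
adds them to the observed stratified cases, **recomputes the
standardisation from the augmented table** (so `sum(e) = sum(o')` in every
run — "the same analyses" begin at standardisation), re-runs the flexible
scan, MEET and every regression, and records the p-values; the default is
`T = 100` runs with `R = 999` inner replicates.

Two design choices matter for interpretation. Imputation seeds vary per
run, but each method's inner Monte Carlo reuses one method-level seed
across runs (common random numbers): run-to-run variation in the reported
p distributions then reflects the imputation alone, and an empty
undiagnosed pool reproduces the observed p-values exactly — a degeneracy
the test suite asserts identically. When only region totals of the pool
are known, `allocate_pool()` spreads them across strata by
largest-remainder rounding against a supplied composition; this fallback
is documented as an approximation.

## Synthetic studies

`simulate_study()` generates complete input bundles with the statistical
structure the analyses assume: a jittered hexagonal lattice scaled to the
configured bounding box with distance-threshold contiguity (1.45 × lattice
spacing, re-bridged if jitter disconnects it) — a deliberate, polygon-free
stand-in for map-derived adjacency with realistic neighbour counts;
log-normal region sizes allocated multinomially so the examinee total is
exact (with a floor of one examinee per region-stratum to keep every
`e_i > 0`); Dirichlet-perturbed stratum compositions; stratum rates rising
steeply with age and doubled for females, rescaled so the homogeneous-risk
expected case total matches the configured target exactly; Poisson case
draws over an optional embedded-cluster risk surface (`embed_cluster()`,
relative risk `rr` inside a connected member set, 1 outside); binomial
screening flow (positivity, confirmatory uptake, the undiagnosed
remainder); and covariates that include the distance to a designated point
source on the eastern edge plus Gaussian-kernel-smoothed fields. The truth
record (risk surface, cluster membership, stratum rates) rides along for
recovery scoring, and `resample_cases()` redraws only the case table on a
fixed design — the efficient form for calibration and power studies.

What the generator does **not** emulate: real municipal polygon geometry,
spatially structured non-participation, migration or evacuation, or
correlation between covariates and risk unless a cluster is embedded where
a covariate is high. Passing calibration and recovery tests on these
bundles therefore demonstrates correctness of the statistical machinery
under the stated model, not robustness to those real-data features.

## Randomness, determinism, problem sizes

Every Monte Carlo component takes an explicit seed, and composite routines
derive named sub-stream seeds from one master via a rolling polynomial
hash (`substream_seed()`), so enabling or disabling one method never
perturbs another's draws and full runs are bit-reproducible — the pipeline
(`run_pipeline()`) writes a manifest echoing seed, parameters and package
version sufficient to reproduce every output byte.

The test suite exercises the statistical guarantees at deliberately chosen
sizes: null calibration of the scan and MEET on 300 independent case
tables of the default 59-region design with `R = 199` replicates and
`k_max = 10` (empirical size 0.053 and 0.037 at nominal 0.05; a
1000-study check during development gave 0.053 and 0.052); exhaustive-
search equivalence of the flexible enumeration on all graphs of up to 8
regions; 95% Wald coverage over 200 synthetic fits of a true log rate
ratio 0.5 (observed 0.96); and cluster recovery (Jaccard > 0.5 in 90% of
20 study-scale draws with an embedded RR = 3 cluster of 5 regions).

## Known limitations

The flexible enumeration is exponential in `k_max` and capped at 25; the
restricted (risk-threshold) scan variant, space-time windows, elliptic
windows, covariate-adjusted scans, spatially structured random-effect
regression (CAR/BYM) and focused score tests are out of scope. Secondary-
cluster p-values are conservative by construction. The MEET grid is a
reconstruction knob, not an estimate: conclusions about "the" clustering
scale are conditional on the grid supplied.
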