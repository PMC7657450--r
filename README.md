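# neuroshare

Whole-brain reward **pattern expression** scoring of trial-level fMRI
responses, linked to **population-level news sharing** by hierarchical
Bayesian models.

## The problem

Can brain responses to news article summaries forecast how widely those
articles are shared by the reading population? Classic analyses summarize
each trial by the mean activity of reward-related regions of interest
(ventral striatum + ventromedial prefrontal cortex). This package implements
the distributed-pattern extension of that analysis: every trial-level beta
image is scored against a continuous whole-brain reward-valuation weight
map, and the resulting per-trial similarity scalar is entered — alongside
ROI activity and self-report ratings — into hierarchical models of log share
counts.

For trial image $B$ and weight map $W$ (z-scores), **pattern expression** is

$$ r_{pa} = \mathrm{cor}\big(B_{pa}[\text{mask}],\ W[\text{mask}]\big), $$

and the within-person model for standardized log shares $y_{pa}$ is

$$ y_{pa} = x_{pa}^\top\beta + x_{pa}^\top u_p + \varepsilon_{pa},\qquad
u_p \sim \mathrm{MVN}\!\big(0,\ \mathrm{diag}(\tau)\,\Omega\,\mathrm{diag}(\tau)\big), $$

with priors $\beta_j \sim N(0,1)$, $\tau_k,\sigma \sim N^+(0,1)$,
$\Omega \sim \mathrm{LKJ}(1)$, sampled by a purpose-built blocked Gibbs
sampler (4 chains × 1000 iterations, 500 warmup, Gelman–Rubin checked
against [0.95, 1.05]). Models are compared by Bayesian $R^2$ and
Pareto-smoothed importance-sampling LOO (LOOIC). Sensitivity analyses:
Monte-Carlo cluster-extent thresholding of the weight map (AlphaSim-style),
removal of clusters overlapping the ROIs, and a 0–40 mm smoothing sweep of
the map.

Because no participant images or share counts are redistributable, the
package ships a **synthetic-study generator** that emulates the analysis'
statistical structure (correlated ROI blobs, a distributed signed weight
map, trial images driven by latent article value, 1–5 ratings, share counts
spanning tens to low ten-thousands) with all ground truth recorded — every
stage of the pipeline is validated against it.

Intended users: cognitive-neuroscience and neuroeconomics researchers who
want a tested, scriptable implementation of pattern-expression forecasting
analyses, or a simulation bench for planning such studies.

## Worked example

```r
library(neuroshare)

## simulate a default-calibration study: 20 participants x 48 articles,
## 40^3 grid of 3 mm voxels, distributed 30-bump reward map
study <- simulate_default_study(generator_params(seed = 1))

## per-trial features: expression, ROI means, rating, log shares
features <- standardize(build_feature_table(study))

## the nested model ladder
m2 <- fit_hierarchical(features, model_spec(c("rating", "roi_mean"), seed = 11))
m3 <- fit_hierarchical(features, model_spec(c("rating", "roi_mean", "expression_r"),
                                            seed = 11))
m3
#> <model_fit: rating + roi_mean + expression_r | participant, 2000 draws>
#>          term    mean   lower  upper  rhat
#>     intercept 0.00157 -0.0609 0.0648 1.000
#>        rating 0.22113  0.1504 0.2862 1.000
#>      roi_mean 0.13760  0.0713 0.2023 0.999
#>  expression_r 0.05531 -0.0116 0.1232 1.000
#>         sigma 0.95839  0.9184 1.0027 1.000
round(bayes_r2(m3)$median, 3)
#> [1] 0.095
```

The `expression_r` row is the standardized within-person effect of
whole-brain pattern expression on an article's (log) population share count,
holding self-reported interest and ROI activity constant — here about 0.06
for a single desk-scale study (the pooled-study estimate is larger; see
below). `compare_loo(m3, m2)` then asks whether that effect improves
out-of-sample prediction:

```r
cmp <- compare_loo(m3, m2)
round(c(delta_looic = cmp$delta_looic, se = cmp$se), 2)
#> delta_looic          se
#>        0.97        3.50
```

A single 960-trial study is underpowered for this comparison; pooling three
replicate studies (per-study standardization, study label — the design the
reference analysis uses) gives `delta_looic = -12.1 (SE 7.7)` at seed 1,
i.e. the expression term clearly improves predictive fit. The one-call
pipeline runs everything, including the masking and smoothing sensitivity
analyses:

```r
res <- run_analysis(analysis_config(seed = 1))
write_report(res, "results/")   # coefficients.csv, r2.csv, loo_comparisons.csv,
                                # sweep.csv, summary.json, run.log
```

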