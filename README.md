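# reportshift

Hierarchical ordered probit (HOPIT) models for **reporting heterogeneity**
in ordinal self-reported health outcomes such as the five EQ-5D-5L
dimensions.

When population groups use a labelled response scale differently, raw
comparisons of reported severity levels mix true health differences with
*cut-point shift*: systematic differences in where groups place the
boundaries between response categories. `reportshift` is for
epidemiologists and health economists who want to separate the two on
large survey data. Latent health is modelled from semi-objective inputs
(diagnosed long-term conditions, a recent-limitation item, and their
prevalence-screened 2-/3-way interactions), while the category thresholds
are functions of reporting covariates (group membership, age–sex cells,
deprivation terciles, healthcare use, survey wave):

```
h*_i  = β'x_i + ε_i,   ε_i ~ N(0, 1)
τ_i1  = λ_1 + γ_1'z_i
τ_ij  = τ_i,j-1 + exp(λ_j + γ_j'z_i),   j = 2..4
y_i = j  ⇔  τ_i,j-1 ≤ h*_i < τ_ij
```

The exponentiated increments keep the thresholds ordered for any
parameter values; the latent and threshold covariate sets are kept
strictly disjoint. Estimation maximizes the survey-weighted
log-likelihood with an analytic score. The headline statistic is the
threshold difference between a focal group and the baseline at
sample-proportion covariate profiles,

```
Δτ_1 = γ_1'(z¹ − z⁰),   Δτ_j = Δτ_{j-1} + exp(λ_j + γ_j'z¹) − exp(λ_j + γ_j'z⁰)
```

with 95% confidence intervals from a parametric bootstrap (coefficient
draws from N(θ̂, V̂); both percentile and SE-method intervals, a contrast
counting as significant only when both exclude zero). Standardized
coefficients, AIC, McFadden's likelihood-ratio index and Count R² round
out the per-dimension report. A synthetic survey generator (Gaussian-copula
comorbidity structure, realistic prevalences and group shares, lognormal
weights) supports validation and parameter-recovery experiments end to end.

## Worked example

```r
library(reportshift)

cfg <- synth_config(n = 20000, seed = 2,
  group_shares = c(white = 0.55, asian = 0.20, black = 0.10,
                   mixed = 0.08, other_eth = 0.07),
  true_lambda = c(0.3, -0.5, -0.6, -0.7))
tab <- synth_generate(cfg)        # respondent table + hidden ground truth
des <- build_designs(tab)         # screen interactions, build x and z
fit <- hopit(tab$mobility, des$latent, des$threshold,
             weights = des$weights, dimension = "Mobility")
fit
#> Survey-weighted hierarchical ordered probit (Mobility)
#>   n = 20000, sum of weights = 19936.9, parameters = 120
#>   log-likelihood = -22664.9879 (null -24372.5467)
#>   converged: TRUE (max |score| = 4.57e-08)

r <- fit_report(fit)
#> loglik -22665.0 | AIC 45570.0 | LR index 0.070 | Count R2 0.584

threshold_contrasts(fit, n_draws = 1000, seed = 2)
#> Threshold contrasts vs baseline (Mobility)
#>   asian        0.159* (0.024)  0.158* (0.027)  0.168* (0.033)  0.220* (0.045)
#>   black        0.306* (0.034)  0.281* (0.037)  0.272* (0.047)  0.237* (0.062)
#>   mixed        -0.001  (0.034)  0.018  (0.038)  0.012  (0.046)  0.090  (0.061)
#>   other_eth    0.162* (0.036)  0.189* (0.042)  0.129* (0.048)  0.223* (0.071)
#>   boundaries: 1|2  2|3  3|4  4|5  (* both CI methods exclude 0)
```

The generator gave the `asian` group a true first-threshold shift of
+0.2 and `black` +0.3 (`mixed` +0.02, `other_eth` +0.15): those groups
rate the same latent health less severely, and the fitted contrasts
recover the shifts within their bootstrap uncertainty while `mixed` is
correctly flat. `export_bubble_table()` flattens the contrasts into a
plot-ready long table; `run_pipeline()` drives the whole analysis
(designs → fits → metrics → contrasts → CSV/JSON bundle) for all five
dimensions from one config, and `compare_specifications()` aligns the
contrasts across sensitivity specifications (covariates reallocated to
the latent equation, or omitted) and flags sign changes.

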