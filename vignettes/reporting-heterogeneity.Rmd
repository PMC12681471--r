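---
title: "Separating latent health from rating behaviour: the HOPIT model in reportshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating latent health from rating behaviour: the HOPIT model in reportshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reportshift)
```

## The problem

Self-reported ordinal health items — such as the five EQ-5D-5L dimensions,
each rated on five severity levels — confound two things: how healthy a
respondent actually is, and how that respondent maps a given health state
onto the labelled response categories. If population groups use the response
scale differently (*reporting heterogeneity*, or cut-point shift), raw
comparisons of reported levels misstate true health differences.

`reportshift` separates the two with a hierarchical ordered probit (HOPIT):
latent health is driven by "semi-objective" inputs (diagnosed long-term
conditions and a recent-limitation item), while the thresholds that cut the
latent scale into reported levels are driven by a disjoint set of
reporting covariates (group membership, age–sex cells, deprivation
terciles, healthcare use, survey wave).

## Model

For respondent $i$ with condition vector $x_i$ and reporting covariates
$z_i$:

$$h^*_i = \beta' x_i + \varepsilon_i, \qquad \varepsilon_i \sim N(0, 1),$$

and the reported level is $y_i = j$ iff
$\tau_{i,j-1} \le h^*_i < \tau_{i,j}$, with thresholds

$$\tau_{i1} = \lambda_1 + \gamma_1' z_i, \qquad
  \tau_{ij} = \tau_{i,j-1} + e^{\lambda_j + \gamma_j' z_i},\ j = 2,\dots,4,$$

and $\tau_{i0} = -\infty$, $\tau_{i5} = +\infty$. The exponentiated
increments guarantee $\tau_1 < \tau_2 < \tau_3 < \tau_4$ for *any*
parameter values, which is the reason for this parametrization. Estimation
maximizes the survey-weighted log-likelihood

$$\ln L = \sum_i w_i \,
  \ln\!\left[\Phi(\tau_{i,y_i} - \beta'x_i) -
             \Phi(\tau_{i,y_i-1} - \beta'x_i)\right].$$

**Identification.** The error variance is fixed at 1 and the latent
equation carries no intercept (it is absorbed into $\lambda_1$). No
covariate may appear in both equations; the design builders enforce this
disjointness and `reallocate_covariates()` re-verifies it after any
sensitivity move. These are the standard normalizations for this model
class; without them the scale and location of the latent index are not
separately identified from the thresholds.

**Assumptions worth stating.** Conditional on $x_i$, the reporting
covariates carry no information about latent health — deprivation,
healthcare use and age–sex placement affect only *where* the thresholds
sit. This is an identifying assumption, not a testable one; the package
therefore ships the sensitivity machinery (reallocation of covariates into
the latent equation, and reduced specifications via the pipeline's `omit`
option) that lets a user see how conclusions move when it is relaxed.

## Interaction screening

The latent design includes, besides the condition main effects and two
limitation dummies, all 2- and 3-way condition interactions whose joint
prevalence is at least 1% of the sample (`min_prevalence = 0.01`).
Prevalence is **survey-weighted** by default, for consistency with weighted
estimation; an unweighted switch exists because either convention is
defensible. Triples are screened on their own joint prevalence,
independently of their sub-pairs. The screen considers condition mains
only, not the limitation dummies.

## Threshold contrasts and their uncertainty

The headline statistic contrasts the threshold set of a focal group
against the baseline at a fixed covariate profile: $z^0$ sets every
reporting covariate to its weighted sample proportion and all group
dummies to zero; $z^1$ flips exactly one group dummy to one. Then

$$\Delta\tau_1 = \gamma_1'(z^1 - z^0), \qquad
  \Delta\tau_j = \Delta\tau_{j-1}
   + e^{\lambda_j+\gamma_j'z^1} - e^{\lambda_j+\gamma_j'z^0},\ j = 2,\dots,4,$$

which is exactly the elementwise difference of the two threshold sets. A
positive $\Delta\tau_j$ means the focal group rates the same latent health
less severely at that boundary. (The recursion necessarily starts at
$j = 2$: the first boundary is the linear case.)

Uncertainty comes from a **parametric bootstrap**: coefficient vectors are
drawn from $N(\hat\theta, \widehat{V})$ (1,000 draws by default), the
contrast is recomputed per draw, and 95% intervals are formed both from
the empirical 2.5/97.5 percentiles and as estimate $\pm 1.96\,$SE with SE
the across-draw standard deviation. A contrast is flagged significant only
when **both** intervals exclude zero. $\widehat V$ is the inverse observed
information at the weighted optimum; because weights make that
interpretation model-based, a design-based sandwich estimator is available
(`vcov_type = "sandwich"`). The MVN draw symmetrizes $\widehat V$ and
floors its eigenvalues at zero, and the exponent arguments in the contrast
are clipped at $\pm 30$ exactly as in the threshold function, so draws in
weakly identified directions cannot produce non-finite contrasts.

## Fit metrics

* **Standardized coefficients**: $\beta$ rescaled by the range of the
  fitted latent index over the observed sample, so the index spans
  $[0, 1]$ after an affine map. The range is taken over the observed
  sample, not all theoretically possible covariate combinations.
* **Likelihood-ratio index**: the default is McFadden's
  $1 - \ln L_{\text{model}} / \ln L_{\text{null}}$, which lies in $[0,1)$
  and matches the magnitudes such indices take in published work. Read
  literally, the alternative wording "one minus the ratio of the null
  log-likelihood to the model log-likelihood" is negative for negative
  log-likelihoods; it is computable via `type = "as_worded"` but is not
  the default.
* **Count R²**: weighted share of respondents whose modal predicted
  category equals the observed one; ties break toward the less severe
  level (a measure-zero event under continuous parameters).
* **AIC** $= 2k - 2\ln L$ with $k$ counting all free parameters
  ($|\beta| + 4 + 4\,|\gamma_j|$).
* The null model for the index is the intercept-only **weighted** ordered
  probit on the same outcome, for comparability with the weighted fit.

## Numerical choices

* Starting values: $\beta = 0$, $\gamma = 0$, and $\lambda$ chosen so the
  baseline thresholds reproduce the weighted cumulative outcome shares
  through $\Phi^{-1}$.
* Optimizer: BFGS on the analytic score, then damped Newton polishing with
  a numerically differenced Hessian; convergence is declared at score
  max-norm $< 10^{-5}$.
* Probabilities are floored at $10^{-300}$ before the log; threshold
  exponent arguments are clipped at $\pm 30$ (with a warning in the
  user-facing threshold function). Unobserved outcome levels leave the
  adjacent threshold region unidentified; the fit proceeds with a warning
  and the flat direction shows up as a huge variance rather than a crash.
* Refitting with identical inputs reproduces identical estimates: nothing
  in the optimizer is stochastic.

## The synthetic generator

Large general-practice surveys of this kind (e.g. the English GPPS) are
restricted-access, so the generator produces tables with the same
*statistical structure* for validation: 15 condition indicators with marginal prevalences from 0.14%
to 17%, correlated through a single-factor Gaussian copula
(loading 0.5) so that multimorbidity exists and the 1% interaction screen
has something to find; a 3-level limitation item tied to the same factor;
five groups with shares 0.878/0.063/0.026/0.010/0.023; ten age–sex cells;
deprivation terciles (optionally group-dependent, to construct
confounding); healthcare-use indicators; wave dummies; and lognormal
survey weights with mean 1 (sdlog 0.5). Outcomes are generated by running
the model forward: $h^* = \beta'x + N(0,1)$ classified against per-row
thresholds. The hidden truth (latent draws, thresholds, parameters) rides
along in attributes, and reclassifying the hidden draws reproduces the
observed outcomes exactly.

True coefficients are fixed round numbers (latent effects 0.08–0.9,
first-threshold group shifts 0.02–0.3); they are generator defaults, not
estimates of any real survey. What the generator does **not** emulate:
item missingness, panel structure, informative weighting (unless the
dependence knob is turned on), within-group heterogeneity, and any
calibrated joint distribution of a real survey. Passing recovery tests
therefore demonstrates the estimator and its inference machinery, not
fidelity to real GPPS-like data.

## Validation designs and problem sizes

Two deliberate deviations from the generator defaults are used in the
validation experiments, both chosen on power grounds before running them:

* **Balanced focal groups.** With survey-realistic shares a 1% group
  contributes only a few hundred rows at validation sample sizes, and its
  upper-threshold coefficients are weakly identified. Recovery and
  coverage experiments therefore use balanced shares (focal group 15–45%),
  so that the focal cut-point shift is estimated with SE ≈ 0.01 at
  n = 50,000 — the scale at which a 0.02 recovery tolerance is a ~2 SE
  statement rather than a coin flip.
* **Less-skewed outcomes.** Validation runs use threshold intercepts
  giving ~5% mass in the top category (instead of the survey's <1%), so
  all four threshold equations are informed by data at moderate n.
* **Design-based SEs for recovery checks.** With heterogeneous weights
  that are independent of the outcome, the model-based observed
  information understates sampling variance by roughly the design effect
  ($E[w^2]/E[w]^2 \approx 1.28$ at sdlog 0.5); a small simulation during
  development confirmed the sandwich estimator tracks the empirical
  sampling SD. Recovery assertions therefore use
  `vcov_type = "sandwich"`.

Problem sizes: unit tests run at hundreds to a few thousand rows; the
ordered-probit reduction check at n = 5,000; single-replicate recovery at
n = 50,000; bootstrap coverage with 100 replicates at n = 20,000 and 500
draws each; the five-dimension end-to-end run at n = 20,000 with 500–1,000
draws. These sizes make the full suite complete in minutes while keeping
Monte-Carlo error well inside the asserted tolerances.

## Limitations

* Cross-sectional only: no random effects or panel linkage across waves.
* No vignette-based identification; the model identifies reporting
  behaviour purely through the condition set and the disjointness
  assumption.
* The observed-information covariance treats weights as likelihood
  multipliers; for strongly informative designs prefer the sandwich
  option.
* Complete-case analysis: rows with missing modelled fields are dropped
  (and counted), never imputed.

## A short example

```{r example, eval = FALSE}
cfg <- synth_config(n = 20000, seed = 1)
tab <- synth_generate(cfg)
des <- build_designs(tab)                       # screen + both designs
fit <- hopit(tab$mobility, des$latent, des$threshold,
             weights = des$weights, dimension = "Mobility")
summary(fit)
fit_report(fit)                                 # standardized beta + fit battery
cts <- threshold_contrasts(fit, n_draws = 1000, seed = 2)
cts                                             # one block per focal group
export_bubble_table(cts)                        # plot-ready long table
```
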