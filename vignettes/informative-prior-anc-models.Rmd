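---
title: "Multilevel models with historical-survey priors for skilled antenatal care"
author: "ancbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel models with historical-survey priors for skilled antenatal care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

National household surveys in the Demographic and Health Survey (DHS) family
interview women in a two-stage design: enumeration areas ("clusters") are
drawn first, then a fixed number of households within each cluster. Women who
recently gave birth report how many antenatal care (ANC) visits they made,
from what kind of provider, and whether the pregnancy was *wanted*,
*mistimed* (wanted later) or *unwanted* at conception. The scientific
question this package addresses is whether an unintended pregnancy lowers a
woman's uptake of skilled antenatal care, after adjusting for her individual,
household and community circumstances.

Two binary outcomes are analysed: at least one visit to skilled health
personnel (`y_any`) and at least the WHO-recommended four such visits
(`y_four`). Women in the same cluster share context (facilities, norms,
distances), so outcomes are correlated within clusters; the estimator is a
random-intercept logistic regression,

$$\text{logit}\,\Pr(y_{ij}=1 \mid u_j) = \mathbf{x}_{ij}'\boldsymbol\beta + u_j,
\qquad u_j \sim \mathcal N(0, \sigma_u^2),$$

fitted with survey weights and summarized as adjusted odds ratios
$e^{\beta}$ with 95% equal-tailed credible intervals. The distinctive
methodological ingredient is the prior: instead of vague priors, each
coefficient receives an independent normal prior whose moments are *elicited
from earlier waves of the same survey programme* — each historical wave is
fitted with flat Normal(0, 10000) priors, and the across-wave mean and
spread of the resulting coefficient estimates become the prior for the
current wave.

Because the real survey microdata are restricted-access, the package ships a
synthetic-data generator that emulates the design, so that every stage of
the pipeline — derivation, screening, elicitation, estimation, diagnostics —
can be exercised and validated against a known truth.

## The synthetic-data generator

`sim_config()` / `generate_wave()` emulate one survey round:

* **Design.** 600 clusters with 30 households each by default, one eligible
  woman per selected household; a woman is an analysis row if she reports a
  live birth in the preceding 3 years (default eligibility probability 0.25,
  giving roughly 4,500 analysis rows out of 18,000 interviews, the scale of
  the 2014 Bangladesh round).
* **Exposure.** Pregnancy intention is drawn from a 3-category distribution
  with default marginals 74.0/15.1/10.9% (wanted/mistimed/unwanted).
* **Covariates.** Education, husband's education and occupation, age band at
  delivery, parity, media access, wealth quintile are drawn from realistic
  categorical marginals. Education and wealth receive a cluster-level tilt
  (log-linear in the category rank, standard deviation `community_sd = 0.6`)
  so that the community-level aggregates derived downstream vary across
  clusters instead of collapsing into one category. Residence and region are
  cluster-level. The "quality of available ANC" covariate has no published
  operationalization, so it is simulated as an opaque standard-normal
  woman-level variable and passed through untransformed.
* **Outcomes.** A single linear predictor
  $\eta_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + u_j$ drives both outcomes
  through outcome-specific intercept offsets. One uniform draw per woman
  thresholds both success probabilities (a comonotone coupling), so each
  outcome has exactly its logistic marginal while `y_four` can never exceed
  `y_any`. Visit counts and provider type are then back-filled consistently
  with the two codings (including a fraction of unskilled-provider visits
  that must count as zero skilled visits). The default offsets (0.367,
  −1.205) were calibrated once, by simulation at the default design, so the
  weighted prevalences sit at the 2014 benchmark levels of roughly 63.8%
  (any skilled visit) and 31.5% (four or more).
* **True effects.** Default intention coefficients are −0.30 (mistimed) and
  −0.37 (unwanted) on the log-odds scale — odds ratios 0.74 and 0.69 —
  with moderate, conventionally signed education/wealth/media/residence
  effects; the cluster standard deviation defaults to $\sigma_u = 0.8$
  (latent ICC 0.16).
* **Weights.** Lognormal with `sdlog = weight_dispersion` (default 0.2,
  a free choice: the survey reports no weight distribution), normalized to
  mean 1. Weights mimic unequal selection; the generator does not reproduce
  the census frame, stratification or non-response mechanics.
* **Panels.** `generate_panel()` stamps independent waves with distinct year
  labels; coefficient drift across waves is whatever the configs say, which
  is how the prior-elicitation machinery is stress-tested.

Everything is reproducible from `config$seed`, and generation restores the
caller's RNG state.

What the simulator deliberately does **not** emulate: correlated covariates,
household-level clustering (the analysis collapses households into the
individual level, as the average number of eligible women per household is
near one), informative weighting (weights are independent of outcomes),
item-nonresponse mechanisms, or PPS frame selection. Recovery results on
synthetic data therefore validate the *estimator and pipeline logic*, not
the substantive conclusions one would draw from real data.

## Derived variables

`derive_variables()` constructs the analysis variables with fixed,
reference-first factor conventions:

* `y_any`/`y_four` from visit counts and provider type; unskilled-provider
  visits count as zero skilled visits.
* Age at delivery banded ≤19 / 20–34 / ≥35; parity ≤2 / >2.
* Media index: `not_exposed` (no weekly access to newspaper, radio or TV),
  `high` (all three weekly), `moderate` otherwise.
* Community aggregates per cluster, computed with the woman's own record
  included (leave-self-in; the alternative leave-one-out convention changes
  each share by at most 1/30 and no category at realistic cluster sizes):
  * literacy: share of literate women ≤25% `low`, (25%, 50%] `moderate`,
    >50% `high`;
  * poverty: `middle_to_richest` if *no* household is in the bottom two
    wealth quintiles, else bottom-two share ≤25% `low`, (25%, 50%]
    `moderate`, >50% `high`;
  * four-visit uptake: `high` only above a strict 50% majority.

  The published category labels overlap at the cut points ("≤25%" and
  "26–50%" cannot both be half-open for a continuous share); the half-open
  convention (left-closed at 25% and 50%) is adopted and tested at the
  boundaries.
* `eligibility_filter()` keeps recent births with complete intention and ANC
  responses and tallies exclusions by first applicable reason
  (no recent birth → missing intention → missing ANC), so complete-case
  analysis is auditable.

## Screening

Candidate confounders are screened per outcome with a design-corrected
chi-square (`chisq_screen`). The Pearson statistic is computed from the
weighted table; its null distribution under clustering and weighting is a
mixture of chi-squares whose weights are the eigenvalues of the generalized
design-effect matrix — estimated here by with-replacement cluster
linearization — and the p-value uses the second-order (Satterthwaite)
Rao–Scott correction. The eigenvalues are computed *relative to the
multinomial covariance at the same estimated proportions*, so with equal
weights and one cluster per row the test collapses exactly to the Pearson
chi-square. The small-sample factor $m/(m-1)$ on the cluster covariance is
omitted for the same reason; it is negligible at hundreds of clusters.

A variable is retained if $p \le 0.20$ for either outcome (the conventional
purposeful-selection reading of a "p = 0.20" screening rule); the exposure
is always retained regardless of its p-value.

Weighted prevalences are reported with logit-scale confidence intervals
using a Kish effective sample size $(\sum w)^2 / \sum w^2$, which keeps
bounds inside [0, 100] and behaves sensibly at degenerate proportions; the
source analysis does not name its CI method, so this is a package choice.

## Prior elicitation

`fit_historical_wave()` fits each earlier wave by MCMC under flat
Normal(0, 10000) priors, with the same derivation, weighting and model
formula as the final fit (community variables re-derived per wave). For each
coefficient, `combine_priors()` sets

* prior mean = arithmetic mean of the wave posterior means;
* prior SD = across-wave sample SD (n−1 denominator) of those means,
  **floored** at the mean of the wave posterior SDs;
* prior variance = SD².

The published rule — "means equal to the average of the previous year's
regression coefficient and variance equal to the square of the regression
coefficient standard deviation" — does not say whether "the standard
deviation" is the spread of the point estimates across waves or the
within-wave posterior SD. The across-wave spread is adopted as the primary
reading (it is the moment estimate of how much the coefficient actually
moves between rounds); the floor guarantees a proper, non-degenerate prior
when waves happen to agree exactly. Elicited variances are therefore always
finite, at most 10,000 in practice, and the elicited mean is invariant to
wave order. Coefficients absent from every historical fit (e.g. a category
unobserved in an old wave) fall back to Normal(0, 10000) with a warning.

## Estimation

**Maximum likelihood.** `fit_ml()` maximizes the weighted marginal
likelihood via `lme4::glmer` with adaptive Gauss–Hermite quadrature
(11 nodes by default). Survey weights are normalized to sum to the sample
size and enter as pseudo-likelihood case weights, so point estimates are
invariant to rescaling all weights by a constant. AIC ($-2\ell + 2k$) and
BIC ($-2\ell + k\log n$) come from this fit, with $k$ counting fixed effects
plus one variance parameter. Complete separation is reported (flag and
warning), never silently repaired.

**MCMC.** `run_mcmc()` samples $(\boldsymbol\beta, \log\sigma_u)$ from the
posterior ∝ weighted marginal pseudo-likelihood × prior. The marginal
likelihood over each cluster intercept is computed by the same adaptive
(mode-centred, curvature-scaled) Gauss–Hermite rule, implemented in C++ and
cross-checked in the test suite against a brute-force Simpson-quadrature
oracle to 1e-4 and against `glmer`'s log-likelihood to machine precision.
The kernel is a random-walk Metropolis whose proposal shape is the
ML covariance (Cholesky factor) and whose single global step scale is
adapted during burn-in only (Robbins–Monro toward 0.234 acceptance), then
frozen, so kept draws form a valid Markov chain. Chains start from jittered
ML estimates. $\sigma_u$ carries a Half-Normal(0, 5²) prior on the SD scale
(weakly informative at the latent-logit scale of the problem; the source
analysis is silent on the variance-component prior) and is sampled on the
log scale with the Jacobian included.

Defaults are 3 chains, 5,000 burn-in and 10,000 kept draws per chain;
pipeline and test runs use shorter, stated chain lengths. Any correct kernel
would do: correctness is defined by the oracle-equivalence and
parameter-recovery checks, not by the kernel. For fixtures with at most two
free parameters, `exact_grid_posterior()` provides a deterministic
trapezoid-grid posterior (σ_u fixed at 0) against which the sampler's means
and SDs are required to agree within 0.01.

**Summaries.** `posterior_summary()` pools kept draws across chains; the OR
point estimate is the posterior mean of $e^\beta$ and the interval the
2.5/97.5 percentiles of the pooled $e^\beta$ draws (equal-tailed,
transformation-equivariant; software that exponentiates a posterior-mean
log-odds instead will differ slightly — an accepted divergence).

## Diagnostics and model comparison

* `gelman_rubin()` computes the classic potential scale reduction factor
  $\hat R_c = \sqrt{((n-1)/n\,W + B/n)/W}$; convergence is declared when
  every parameter has $\hat R_c < 1.1$ (conventional cut-off).
* `icc_latent()` uses the latent-response decomposition
  $\sigma_u^2 / (\sigma_u^2 + \pi^2/3)$, the standard ICC for multilevel
  logit models; it is evaluated at the posterior mean of $\sigma_u^2$ for
  Bayesian fits and at $\hat\sigma_u^2$ for ML fits.
* `model_sequence()` fits the nested sequence per outcome — M0 (null:
  intercept + cluster effect), M1 (individual + household factors), M2
  (community factors only), M3 (all) — and tabulates AIC/BIC/ICC/max
  $\hat R_c$; the preferred model is the converged fit with smallest AIC,
  ties broken by BIC. (The source describes the same four fits with
  inconsistent numbering — "Model 1…Model 3" in the methods, "Model 4" in
  the results; the M0–M3 naming here covers the same sequence.) AIC/BIC are
  reported from the ML fit only, as they are not Bayesian quantities.

## The pipeline

`run_pipeline()` chains simulate (or load CSV waves) → derive → screen →
elicit → fit → diagnose → report, writing every intermediate artifact
(waves + truth sidecars, derived data, exclusion audit, Table-1/2-shaped
CSVs, prior and posterior JSON, rendered Table-3-shaped OR tables, a
structured log) under one output directory. All randomness flows from a
single root seed with fixed per-stage offsets, so a rerun with the same
configuration is byte-identical. Configuration is a named list or YAML file
checked by `validate_run_config()` (a hand-written validator; field
presence, ranges, wave-file existence before any fitting).

## Numerical choices and problem sizes

* Quadrature: 11 adaptive Gauss–Hermite nodes by default (7 in the bulk
  simulation tests); the Simpson oracle uses 10⁴ panels over ±10σ.
* Grid oracle: 10⁵ points on [−10, 10] in 1D, 401² in 2D; oracle fixtures
  use informative priors so the posterior is comfortably inside the grid.
* The test suite runs its simulation studies at reduced but honest sizes
  chosen to keep the whole suite in the minutes range: oracle fixtures at
  n = 20–40; recovery at 150 clusters × 30 households with 50 replicates;
  ICC recovery at the full 600-cluster design; screening calibration with
  500 null replicates of n = 5,000; the shrinkage comparison with 20 paired
  replicates at 60 × 10. The acceptance script runs the full pipeline at
  600 × 30 with ~25% eligibility (≈4,500 analysis rows, the study scale).
* Tie-breaks and degenerate inputs: boundary σ̂_u = 0 is accepted (ICC 0);
  MCMC then explores tiny σ on the log scale under the Half-Normal prior;
  a 50% community four-visit share is `low` (strict majority for `high`);
  empty clusters are errors, not silent NAs.

## Known limitations

* The published real-data odds ratios, ICCs and information criteria are
  computed on restricted microdata and serve only as narrative benchmarks;
  nothing in this package reproduces them bit-for-bit, and the published
  "quality of antenatal care" row is internally inconsistent and is not
  reproduced.
* Marginal (single-η, comonotone) outcome coupling is one of several
  defensible generative choices; it fixes both outcome margins and the
  nesting constraint but does not model the visit-count process itself.
* The pseudo-likelihood treatment of weights is first-order: it targets the
  weighted point estimate but, like all single-weight approaches, does not
  propagate the full design variance into the posterior spread.
* Random-walk Metropolis mixes adequately at the model sizes used here
  (tens of coefficients); for much larger formulas a gradient-based kernel
  would be the natural upgrade, and the modular target (likelihood in C++,
  prior in the spec) makes that a local change.
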