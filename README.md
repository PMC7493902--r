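# ancbayes

Bayesian multilevel logistic models with historical-survey priors for
skilled antenatal-care uptake.

## What this package is for

In two-stage cluster household surveys of the DHS family, women who recently
gave birth report their antenatal care (ANC) visits and whether the
pregnancy was **wanted**, **mistimed** or **unwanted** at conception. The
question for maternal-health researchers is whether unintended pregnancy
lowers the uptake of skilled ANC — coded as *at least one* skilled visit and
*at least four* skilled visits (the WHO recommendation) — after adjusting
for individual, household and community factors.

The estimator is a survey-weighted random-intercept logistic regression,

```
logit Pr(y_ij = 1 | u_j) = x_ij' β + u_j,   u_j ~ N(0, σ_u²),
```

with women *i* nested in clusters *j*, fitted two ways: by adaptive
Gauss–Hermite maximum likelihood (starting values, AIC/BIC) and by MCMC
under independent per-coefficient normal priors. The distinctive ingredient
is **prior elicitation from history**: each earlier wave of the survey is
fitted with flat Normal(0, 10000) priors, and for every coefficient the
across-wave mean and spread of the estimates become the informative prior
for the current wave. Results are reported as adjusted odds ratios (aOR)
with 95% equal-tailed credible intervals, alongside the latent-scale
intra-class correlation σ_u²/(σ_u² + π²/3), Gelman–Rubin convergence
diagnostics, and a null/M1/M2/M3 model-comparison table.

Real DHS microdata are restricted-access, so the package includes a
first-class synthetic-data generator (`sim_config()`, `generate_wave()`,
`generate_panel()`) that emulates the survey design — 600 clusters × 30
households, ~25% of women with a recent live birth, a 74/15/11% intention
split, lognormal survey weights, cluster-tilted covariates — from a known
multilevel truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(ancbayes)

# simulate a four-wave panel at demo scale (100 clusters x 10 households)
years <- c(2004L, 2007L, 2011L, 2014L)
configs <- lapply(seq_along(years), function(i)
  sim_config(n_clusters = 100, households_per_cluster = 10,
             eligible_fraction = 1, year_label = years[i], seed = 100 + i))
waves <- generate_panel(configs)

# derive the analysis variables for the current wave
d2014 <- derive_variables(eligibility_filter(waves[["2014"]]$women)$records)

# weighted prevalence of pregnancy intention (Table-1 style)
weighted_prevalence(d2014$intention, d2014$weight)
#>   category   n prevalence_pct ci_lower_pct ci_upper_pct
#> 1   wanted 753           74.9         72.1         77.6
#> 2 mistimed 147           14.9         12.8         17.3
#> 3 unwanted 100           10.2          8.4         12.2

# elicit an informative prior for the intention model from 2004/2007/2011
spec <- anc_model_spec("y_four", terms = c("intention", "education"))
prior <- elicit_prior(waves[c("2004", "2007", "2011")], spec,
                      n_chains = 2, n_burnin = 500, n_kept = 1000, seed = 1)
prior
#> <prior_spec> elicited (waves 2004, 2007, 2011)
#>                        mean     var
#> (Intercept)         -0.9812 0.05614
#> intention_mistimed  -0.2832 0.04939
#> intention_unwanted  -0.2740 0.06487
#> education_primary    0.0917 0.06533
#> education_secondary  0.2392 0.05500
#> education_higher     0.5883 0.10000

# fit the 2014 wave under the elicited prior
ml <- fit_ml(spec, d2014)
mc <- run_mcmc(spec, d2014, prior, n_chains = 3, n_burnin = 1000,
               n_kept = 2000, seed = 42, ml_fit = ml)
posterior_summary(mc)
#>                 term beta_mean beta_sd    or or_lower or_upper
#>          (Intercept)    -1.042   0.123 0.355    0.279    0.445
#>   intention_mistimed    -0.362   0.153 0.705    0.515    0.944
#>   intention_unwanted    -0.331   0.180 0.730    0.507    1.024
#>    education_primary     0.168   0.148 1.196    0.876    1.579
#>  education_secondary     0.348   0.145 1.431    1.068    1.873
#>     education_higher     0.445   0.172 1.584    1.134    2.186
#> sigma_u^2 posterior mean 0.7895 (latent ICC 0.1935), 6000 draws

cc <- convergence_check(mc)
sprintf("max Rc = %.3f (converged: %s); AIC = %.1f; BIC = %.1f",
        cc$max_rc, cc$converged, ml$aic, ml$bic)
#> "max Rc = 1.010 (converged: TRUE); AIC = 1212.5; BIC = 1246.9"
```

Reading the output: women with a mistimed pregnancy have posterior-mean odds
of attaining four or more skilled visits about 0.71 times those of women
with a wanted pregnancy (`odds_reduction_pct(0.705)` ≈ 29% lower odds), with
a 95% credible interval 0.52–0.94; the simulation truth behind these data is
an odds ratio of 0.74 (mistimed) and 0.69 (unwanted) and σ_u = 0.8 (latent
ICC 0.16). Every chain passed the Gelman–Rubin check (max Rc < 1.1).

The same analysis runs as one orchestrated, fully seeded pipeline
(`run_pipeline()`), which writes wave CSVs, the derived data and exclusion
audit, screening tables (design-corrected Rao–Scott chi-square with the
p ≤ 0.20 retention rule), elicited priors, posterior JSON and rendered
OR tables to an output directory; `inst/scripts/ancpipe.R` exposes
`simulate` / `derive` / `screen` / `elicit` / `fit` / `report` subcommands
over the same functions.

## Package layout

| module | contents |
|---|---|
| `R/synthetic_data.R` | survey-wave simulator with known multilevel truth |
| `R/derived_variables.R` | eligibility, outcome coding, media index, community aggregates |
| `R/screening.R` | weighted prevalences, Rao–Scott chi-square, p ≤ 0.20 selection |
| `R/prior_elicitation.R` | flat-prior historical fits, across-wave prior combination |
| `R/multilevel_model.R` | ML fit (lme4), MCMC sampler, posterior summaries, grid oracle |
| `R/diagnostics.R` | Gelman–Rubin, latent ICC, null/M1/M2/M3 comparison |
| `R/pipeline.R` | orchestration, YAML config, table rendering |
| `src/agq.cpp` | adaptive Gauss–Hermite marginal likelihood + RWM kernel |

See the vignette (`vignettes/informative-prior-anc-models.Rmd`) for the
model, the generator's assumptions, and all numerical choices.
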