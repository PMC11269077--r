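# chdrisk

Risk stratification and in-hospital mortality prediction for congenital
heart surgery, as a tidyverse-native R package.

## The problem

After surgery for congenital heart disease, in-hospital mortality differs
enormously between procedures — from well under 1% for a routine septal
defect closure to the most dangerous palliative operations. Two questions
drive risk adjustment in this field:

1. **Procedure level.** What is each procedure's true mortality, given that
   many procedures are performed so rarely that their raw death rates are
   nearly meaningless (3 deaths in 4 Norwood operations is *not* a 75%
   mortality estimate anyone should report)? And how should procedures be
   grouped into a small number of ordered risk categories?
2. **Patient level.** Given a patient's preoperative state — oxygen
   saturation, age, ventilation, shunt anatomy, operation history — and the
   procedure's risk category, what is *this* patient's probability of dying
   in hospital?

chdrisk implements a complete two-stage answer:

- a **Bayesian binomial random-effects (shrinkage) model** — deaths
  `d_j ~ Binomial(n_j, p_j)` with `logit(p_j) = mu + b_j`,
  `b_j ~ N(0, tau^2)` — fitted either by a hand-written, seeded, adaptive
  MCMC sampler with a split-R̂ convergence gate, or by a deterministic
  empirical-Bayes quadrature route;
- **exact dynamic-programming segmentation** of the shrunk, rate-ordered
  procedures into contiguous risk categories minimising case-weighted
  within-category variance, with the number of categories selected by BIC;
- a **gradient-boosted mortality classifier** (xgboost engine) with
  recursive feature elimination by gain importance, hyperparameter grid
  search by stratified cross-validated AUC, Youden-index operating
  thresholds, and percentile-bootstrap AUC confidence intervals;
- a **synthetic registry generator** (heavy-tailed procedure volumes,
  logit-normal procedure heterogeneity, mixed covariates with missingness,
  calibrated logistic outcome) so every stage is testable without access to
  protected hospital data.

The package ships a reference table of 102 congenital heart surgery
procedures (24,685 operations, 591 deaths, overall mortality 2.4%) with
published unadjusted and model-based mortality columns and three risk
gradings.

## Worked example

Shrink the reference table, stratify it, and look at the Norwood operation:

```r
library(chdrisk)
library(dplyr)

tab  <- apply_inclusion_rules(chd_table2())
fit  <- fit_procedure_shrinkage(tab, method = "mcmc", seed = 1)
glance(fit)
#> # A tibble: 1 × 6
#>   n_procedures    mu   tau population_rate method max_rhat
#>          <int> <dbl> <dbl>           <dbl> <chr>     <dbl>
#> 1          102 -3.61  1.66          0.0263 mcmc       1.01

tidy(fit) |>
  filter(procedure %in% c("VSD membranous repair", "Arterial switch repair",
                          "Norwood operation")) |>
  select(procedure, cases, deaths, raw_rate, posterior_mean,
         credible_low, credible_high)
#> # A tibble: 3 × 7
#>   procedure      cases deaths raw_rate posterior_mean credible_low credible_high
#>   <chr>          <int>  <int>    <dbl>          <dbl>        <dbl>         <dbl>
#> 1 VSD membranou…  7910     23  0.00291        0.00300      0.00200       0.00425
#> 2 Arterial swit…   456     87  0.191          0.189        0.153         0.226
#> 3 Norwood opera…     4      3  0.75           0.441        0.107         0.823
```

The high-volume septal repair barely moves (0.291% → 0.300%); the Norwood
raw rate of 75% is shrunk to 44% with an honest, very wide credible
interval. Stratification then runs the exact dynamic program over the
rate-ordered procedures and picks the number of categories by BIC:

```r
strat <- select_num_categories(tab, fit)
glance(strat)
#> # A tibble: 1 × 4
#>       K homogeneity   bic n_procedures
#>   <int>       <dbl> <dbl>        <int>
#> 1     6       0.810  338.          102

strat$category_summary
#> # A tibble: 6 × 6
#>   risk_category n_procedures cases deaths pooled_rate mean_model_rate
#>           <int>        <int> <int>  <int>       <dbl>           <dbl>
#> 1             1           16 13567     33     0.00243         0.00329
#> 2             2           41  6377    120     0.0188          0.0203
#> 3             3           17  3065    172     0.0561          0.0551
#> 4             4           14   889    102     0.115           0.108
#> 5             5            8   727    139     0.191           0.183
#> 6             6            6    60     25     0.417           0.312
```

BIC selects K = 6 here; a 5-category solution sits ~4.5 BIC points away,
well inside the 2·log(N) ≈ 20.2 equivalence band, so a 5-level scheme is
statistically indistinguishable (the K-versus-BIC trace is in
`strat$trace`, or `autoplot(strat)`). The recovered ordering agrees
strongly with the published 5-level stratification column
(Spearman ρ ≈ 0.94).

For the patient level, `run_pipeline(pipeline_config(...))` chains the
whole analysis — simulate or load procedures, shrink, stratify, simulate
patients, split 3:1, optional feature elimination, grid search, evaluate —
writing every stage artifact with an MD5 manifest. On a 20,000-patient
synthetic registry the boosted classifier reaches a test AUC of 0.851
(95% bootstrap CI 0.815–0.886), clearly ahead of the ordinal risk-category
score alone (AUC 0.680), with sensitivity 0.72 and specificity 0.84 at the
Youden-optimal threshold.

## Documentation

See the methods vignette (`vignettes/methods.Rmd`) for the model, priors,
sampler moves, the empirical-Bayes route, the homogeneity and BIC
definitions, generator calibration, and testing strategy; every exported
function has roxygen documentation with examples.
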