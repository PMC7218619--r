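# apcbayes

Bayesian age–period–cohort (APC) modelling and 10-year projection of
dichotomous symptom rates from survey count tables.

Epidemiological surveys of self-reported symptoms such as pain record, for
each gender stratum, how many subjects were at risk and how many reported
the symptom in each five-year age group and five-year calendar period.
Three time scales drive such rates: age at observation, period of
observation (environmental and reporting effects shared by everyone
observed at the same time), and birth cohort (exposures that follow people
born at the same time through life). `apcbayes` gives analysts of such
tables the full workflow: descriptive rate tables, a smoothing Bayesian APC
model, model comparison, and forward projection with credible bands — plus
a synthetic-data generator so every stage can be exercised and validated
without access to restricted survey data.

## The model

Counts are organised in a Lexis table with age groups *i* = 1…I (youngest
first), periods *j* = 1…J (earliest first), and cohort diagonals indexed by

    k = M (I − i) + j,   k = 1…K = M (I − 1) + J,

where *M* is the ratio of the age-group width to the period width. For the
canonical grid of 14 five-year age groups (31–35 … 96–100) and 5 five-year
periods (1991–1995 … 2011–2015), K = 18, collapsing into 9 disjoint
ten-year birth decades (1891–1900 … 1971–1980).

Event counts are modelled as Poisson,

    y_ijk ~ Poisson(n_ijk λ_ijk),
    log λ_ijk = μ + α_i + β_j + γ_k (+ z_ij),

with intercept μ, age effects α, period effects β, cohort effects γ and an
optional iid Gaussian overdispersion term z per cell. Each effect vector
gets an intrinsic random-walk smoothing prior of order 1 or 2 (RW1
penalises squared first differences, RW2 squared second differences), its
precision a diffuse Gamma(1, 0.00005) hyperprior; the overdispersion
precision gets Gamma(1, 0.005). Identifiability is imposed by sum-to-zero
constraints on each effect (and, for the full RW2 model, a zero linear
trend in γ — see the methods vignette). Inference is by a
Metropolis-within-Gibbs sampler written in C++; model choice uses the
Deviance Information Criterion (lower is better), with a near-tie rule that
prefers the complete APC model with RW2 priors. Projections extend β (and
the new cohort diagonals of γ) through the random-walk predictive
distribution of each posterior draw and summarise predictive rates into
nested central credible bands, the narrowest conventionally 10%, the widest
95%.

## Worked example

```r
library(apcbayes)

table <- generate_apc_table(default_truth("female"), seed = 1)
observed_rates(table, "period")
#>   margin level label     numerator denominator  rate
#> 1 period     1 1991-1995     32461       75240 0.431
#> 2 period     2 1996-2000     34501       75240 0.459
#> 3 period     3 2001-2005     35329       75240 0.470
#> 4 period     4 2006-2010     36969       75240 0.491
#> 5 period     5 2011-2015     38626       75240 0.513
```

The observed rate of the simulated female stratum climbs from 43% to 51%
across periods. Fit the full APC model with RW2 priors and inspect it:

```r
fit <- fit_apc(
  table,
  apc_model_spec(effects = c("age", "period", "cohort"), rw_order = 2),
  mcmc_config(n_iter = 30000, burnin = 8000, thin = 20, chains = 2, seed = 1)
)
glance(fit)
#>   model          DIC    pD mean_deviance n_draws chains rhat_mu min_acceptance
#> 1 apc-rw222-od  774.  47.8          726.    2200      2    1.00          0.266

tidy(fit) |> dplyr::filter(effect == "period")
#>   effect level label     mean_log ... mean_RR
#> 1 period     1 1991-1995  -0.0784 ...   0.925
#> 5 period     5 2011-2015   0.0802 ...   1.08
```

DIC = 774 with about 48 effective parameters; split R-hat near 1 says the
two chains agree. The period rate ratios rise monotonically from 0.93 to
1.08: relative to the average period, the most recent one is a risk factor
for reporting the symptom. Project ten years (two periods) ahead, carrying
forward the at-risk counts of 2011–2015:

```r
proj <- project_rates(fit, horizon = 2)
projection_delta(proj, table) |> head(4)
#>   age_start age_end baseline_rate projected_rate   delta delta_pct_points
#> 1        31      35         0.395          0.397 0.00260            0.260
#> 2        36      40         0.380          0.419 0.0395             3.95
#> 3        41      45         0.444          0.445 0.00128            0.128
#> 4        46      50         0.451          0.469 0.0176             1.76
```

`delta_pct_points` is the projected change in percentage points between the
last observed period and 2021–2025 per age group. `autoplot(proj, table)`
draws the fan chart (observed points, predictive mean, nested 10–95%
bands); `autoplot(fit)` draws the rate-ratio curves. `run_apc_pipeline()`
chains all stages (rates → candidate fits → DIC selection → effect
summaries → projection) and writes CSVs plus a run log;
`inst/scripts/apc-pipeline.R` wraps it for the shell.

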