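---
title: "Bayesian age-period-cohort modelling of symptom rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian age-period-cohort modelling of symptom rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the model and its assumptions, the parameters that matter and their
defaults, how the sampler resolves the APC identifiability problem, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The data and the model

The unit of analysis is a Lexis table: an $I \times J$ grid of cells, one
per (five-year age group, five-year calendar period), holding subjects at
risk $n_{ij}$ and event counts $y_{ij}$ for one stratum (strata — here
genders — are always separate tables and are never pooled implicitly,
because the effects of interest differ by gender). Birth cohorts run along
the grid's diagonals and are indexed by

$$k = M\,(I - i) + j, \qquad k = 1,\dots,K = M\,(I-1)+J,$$

with $M$ the ratio of age-group width to period width, so $k=1$ is the
earliest-born (oldest) cohort and larger $k$ are later-born. With $I = 14$
age groups (31–35 … 96–100), $J = 5$ periods (1991–1995 … 2011–2015) and
$M = 1$, there are $K = 18$ cohort diagonals. Each diagonal's birth window
is $[\text{period start} - \text{age end},\ \text{period end} -
\text{age start}]$; adjacent windows overlap, and grouping them by the
decade in which the window opens yields 9 disjoint ten-year birth
intervals, 1891–1900 through 1971–1980. `cohort_decades()` reports both
the raw diagonal index and the decade label. Interval labels are closed on
both ends ("1991–1995"); internal arithmetic uses start years only.

Counts follow a Poisson likelihood with a log-linear decomposition,

$$y_{ijk} \sim \text{Po}(n_{ijk}\lambda_{ijk}), \qquad
  \log \lambda_{ijk} = \mu + \alpha_i + \beta_j + \gamma_k\ (+\,z_{ij}),$$

where $\mu$ is the general level and $\alpha$, $\beta$, $\gamma$ are age,
period and cohort random effects. The event probability is modelled as a
Poisson rate even though the data are proportions; this is the standard
approximation of the APC literature and is adequate at the rates (0.3–0.55)
and denominators (10^3^–10^5^) this package targets. The optional
overdispersion term $z_{ij} \sim N(0, 1/\tau_z)$ absorbs extra-Poisson
cell-level noise and is included by default.

### Priors

Each included effect vector $u$ receives an intrinsic random-walk
smoothing prior of order 1 or 2:

$$p(u \mid \tau_u) \propto \tau_u^{r/2}
  \exp\!\Big(-\frac{\tau_u}{2}\, q_d(u)\Big), \qquad r = m - d,$$

where $q_1$ is the sum of squared first differences and $q_2$ of squared
second differences of the length-$m$ vector. RW1 shrinks toward a constant
level, RW2 toward a linear trend; the prior is flat on its null space
(constants for RW1; constants and linear trends for RW2), which is exactly
what lets the data determine the overall trend while the prior only
penalises roughness. The assumption behind both is that effects are
expected to be constant a priori, so both small and large deviations from
a constant rate can be detected.

Hyperpriors are deliberately non-informative Gamma distributions on the
precisions: shape 1 and rate 0.00005 for each effect precision, shape 1
and rate 0.005 for the overdispersion precision (equivalently, log-gamma
on the log precisions). These are the stock defaults of the Bayesian APC
methodology. All normalising constants are retained in every density so
that deviance summaries are comparable across model specifications. The
intercept carries a flat prior.

### Identifiability

Because cohort = period − age, the three effects are linearly dependent;
two constraints are needed. The first is conventional: each effect vector
is constrained to sum to zero over the observed range, so $\mu$ carries
the overall level and effects are interpretable as log rate ratios
(RR $= e^{\text{effect}}$, with RR $>1$ marking a level as a risk factor
relative to the constrained mean; by construction the RRs of one effect
multiply to 1 in every posterior draw).

The second is subtler. In the full APC model with RW2 priors on all three
effects, the posterior is *exactly constant* along one more direction: add
a linear trend $c\,(k - \bar k)$ to $\gamma$ and subtract the matching
linear trends from $\alpha$ and $\beta$, and neither the likelihood (the
linear predictor is unchanged cell-wise) nor any RW2 penalty (invariant to
linear shifts) changes. An exact MCMC sampler therefore performs an
unbounded random walk along that direction and has no stationary
distribution; in experiments, credible-interval calibration visibly
degraded as chains lengthened. The sampler consequently works on the
quotient space: after every sweep it selects the representative with zero
linear trend in the cohort effect, folding the trend into the age and
period effects (a pure relabelling along the flat direction, applied only
when all three effects are present with RW2 priors — with an RW1 prior on
any effect the direction is penalised and proper, and the projection
would distort the posterior, so it is not applied). Reported cohort
effects are therefore curvature-only, and secular drift is carried by the
period effect — the common identification convention in APC analysis, and
the one under which projections extrapolate drift through $\beta$. For
models including RW1 priors, trends within each effect remain identified
only up to the prior's smoothing; this is a known caveat of the model
class, visible in practice as unstable estimated trends for the youngest
age groups when few periods are observed.

## Inference

`fit_apc()` runs a Metropolis-within-Gibbs sampler (C++ core):

* single-site Gaussian random-walk Metropolis updates for $\mu$, each
  effect level, and each overdispersion cell, with likelihood deltas
  computed only over the cells a coordinate touches (a row for an age
  level, a column for a period level, a diagonal for a cohort level);
* conjugate Gamma updates for every precision:
  $\tau_u \mid u \sim \text{Gamma}(a + r/2,\ b + q_d(u)/2)$;
* hard sum-to-zero re-centering after every sweep, the subtracted mean
  absorbed into $\mu$ (the linear predictor is unchanged), plus the
  null-space projection described above;
* proposal scales adapted every 100 iterations during burn-in toward a
  20–40% acceptance rate (multiplying by 1.25 / 0.8 outside that window),
  then frozen so the retained draws satisfy detailed balance;
* R's RNG throughout, so identical seeds give bitwise-identical draws.

Defaults: 50,000 iterations, 10,000 burn-in, thinning 20, 2 chains
(`mcmc_config()`). Initial effect values are centred log marginal rates,
with the cohort init's linear component projected out (folded into the age
and period inits) so the chain starts on the representative it samples on;
a non-finite initial log posterior raises an error instructing
re-initialization. Convergence is monitored by split-$\hat R$ on $\mu$ and
the log precisions; values below 1.05 at the defaults are expected on
tables like the synthetic defaults.

Model comparison uses the Deviance Information Criterion,
$\mathrm{DIC} = \bar D + p_D$ with $D = -2\log L$ and $p_D = \bar D -
D(\hat\theta)$ evaluated at the posterior mean of all structural
parameters; $p_D$ can be negative on pathological fits and is reported as
computed, never clipped. `select_model()` fits a candidate list and
returns the lowest-DIC model, except that a full-APC/RW2 candidate within
`near_tie_threshold` (default 2, a conventional "similar DIC" margin) of
the minimum is preferred, RW2 being the standard smoothing target.
Candidates that fail to fit are flagged with a warning and skipped.

## Projection

`project_rates()` extrapolates each posterior draw through the random-walk
predictive distribution: for horizon $h = 1,\dots,H$,

$$\beta_{J+h} \sim N(\beta_{J+h-1},\ 1/\tau_\beta) \quad (\text{RW1}),
\qquad
\beta_{J+h} \sim N(2\beta_{J+h-1} - \beta_{J+h-2},\ 1/\tau_\beta)
\quad (\text{RW2}),$$

and likewise for the $H$ new cohort diagonals entering the grid from the
youngest age (the maximal index grows from $M(I-1)+J$ to $M(I-1)+J+H$, so
$H$ new values are needed whatever $M$ is; they are extrapolated by the
same-order RW as fitted). Extended segments are *not* re-centred — the
sum-to-zero constraint identifies the observed range only. In the
infinite-precision limit RW1 continues the last value and RW2 the last
slope exactly, which the tests assert. Overdispersion in future cells is
integrated over fresh $z \sim N(0, 1/\tau_z)$ draws by default
(predictive intervals should reflect all modelled variability); a
structural-only option excludes it.

Predictive rate draws $\lambda = e^\eta$ per (age group, future period)
cell are summarised into a mean, a median and central credible bands at
the configured levels (default 10, 25, 50, 75, 95%): a "10% band" is the
45th–55th percentile interval around the predictive median, "95%" the
widest band shown, and nesting across levels is automatic because all
bands are order statistics of one draw set. Requesting a level finer than
the draw count can resolve raises an error naming the minimum number of
draws. At-risk counts default to carrying the last observed period's $n$
forward per age group; user-supplied future counts are accepted. The
default horizon is $H = 2$ five-year periods, a 10-year projection.
`projection_delta()` reports projected minus observed baseline rate per
age group in rate points and percentage points. Rates are Poisson means
and are not truncated at 1; with the default generative ranges they stay
well below it.

## The synthetic-data generator

`default_truth()` freezes, per gender, a generative parameter set on the
canonical 14 × 5 grid emulating the structure of large harmonized
multi-cohort ageing surveys of self-reported pain: female level above male
(μ = log 0.45 vs log 0.375, expected totals 0.47 vs 0.39); a mildly
increasing age effect (±0.08 on the log scale) plateauing from the 81–85
group; a monotone increasing period effect (±0.08); a cohort effect that
is an exactly symmetric concave parabola across the 18 diagonals
(peak-to-trough 0.16, peaking mid-range, i.e. births in the 1920s–1940s);
overdispersion SD 0.03; and at-risk counts of 10^3^–10^4^ per cell
concentrated in the 51–70 age classes. These values were chosen once so
that all cell rates lie in [0.3, 0.55], the range such surveys report, and
are deliberately never tuned afterwards. The symmetric parabola also makes
the truth carry no linear cohort component, so it is expressed in the same
identification convention the sampler reports (zero linear trend in γ) and
recovery experiments compare like with like.

`generate_apc_table()` draws $z$, forms $\lambda$, and draws $y \sim
\text{Poisson}(n\lambda)$. A Poisson draw can exceed $n$ with small
probability (the model is a rate approximation to a proportion); such
cells are capped at $y = n$ to keep tables valid and the cap is logged via
a message. At the default rates and denominators the cap essentially never
triggers. `make_fixture_suite()` writes deterministic CSV fixtures (male,
female, a 4 × 3 debug grid, an intercept-only table) with full-precision
YAML truth manifests, so recovery tests never hard-code true values.

What the generator does **not** emulate: the composition of real
harmonized datasets from heterogeneous studies (varying instruments,
attrition, missingness, unequal populations across periods), sampling
without replacement within a closed population, or binomial sampling
proper. Passing tests therefore demonstrate that the machinery recovers
the structure it assumes — not that any particular real dataset satisfies
those assumptions.

## Numerical choices and degenerate inputs

* Sum-to-zero is enforced to better than 1e-10 on every retained draw
  (exact subtraction each sweep); the `apc_params` validator uses the same
  tolerance.
* The linear predictor matrix is rebuilt from the state every 1000
  iterations to stop incremental round-off drift.
* Rates are stored at full precision; display rounding (1 decimal of
  percent) is left to output formatting. Empty margin levels (zero
  denominator) yield missing rates, never zero.
* Tables whose age width is not an integer multiple of the period width
  are accepted for age/period/total rate arithmetic, but cohort indexing
  and model fitting raise an informative error (`m_ratio` is `NA`).
* `y > n` cells, duplicate or missing grid cells, and unequal interval
  widths are rejected at construction with messages naming the offending
  rows.
* Effect vectors shorter than `order + 1` are rejected by the RW penalty
  with the minimum length named.

## Problem sizes used by the test suite

The suite exercises the full stack at sizes chosen to make the Monte-Carlo
checks sharp while keeping a default run short: oracle equivalence of the
log posterior on 50 random instances with $I, J \le 5$; a dense-grid
quadrature comparison on a 2 × 2 table with precisions pinned by a
near-degenerate hyperprior (2 × 10^5^ iterations, agreement within 2%);
and a parameter-recovery experiment of 20 replicate tables from the
default male truth, each fitted with 2 chains of 40,000 iterations, in
which 95% credible intervals are required to cover at least 85% of the
true effect levels and the full APC model to beat the AP-only model on DIC
in at least 16 of 20 replicates (observed: ~96% coverage and 20/20).

## Known limitations

* Inference is exact-MCMC but single-site; for much larger grids than
  ~20 × 20 a blocked or gradient-based sampler would mix faster.
* DIC is the only model-comparison criterion, matching the analysis
  tradition this package serves; no WAIC/LOO.
* The Poisson-rate approximation to proportions breaks down as rates
  approach 1; the generator guards its own truths but user tables near
  the boundary deserve a binomial model instead.
* Projections condition on carried-forward at-risk counts; they are
  rate projections, not population forecasts, and ignore demographic
  dynamics.
* No covariates beyond age, period and cohort; no harmonization of
  heterogeneous survey items into an analysis variable (upstream of this
  package).
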