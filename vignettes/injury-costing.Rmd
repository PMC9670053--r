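---
title: "Costing occupational injuries from the employer's perspective"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing occupational injuries from the employer's perspective}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injurycost)
```

## The costing model

`injurycost` implements a prevalence-based, single-year cost-of-illness
analysis of occupational injuries from the employer's perspective, driven by
workers' compensation claim records (one row per injured worker). Three
quantities are produced.

**Direct costs** (medical care plus compensation payments) are estimated
*top-down*: rather than summing per-case bills, the median medical cost and
the median compensation per claim are added and multiplied by the total
number of claims,

$$\text{total direct} = (\tilde{m}_{\text{medical}} +
  \tilde{m}_{\text{compensation}}) \times N.$$

Medians are used throughout because claim costs are strongly right-skewed;
a handful of catastrophic claims would dominate a mean. Compensation is also
broken down by the four disability classes of compensation practice
(temporary total, permanent partial, permanent total, death). Employer
premium payments can be carried alongside the report but never enter the
direct total: a premium is an insurance transfer, not a cost caused by the
year's injuries. `allocate_total()` provides the complementary top-down
primitive — splitting a known aggregate across categories by non-negative
weights, with a largest-remainder correction so the cent-rounded parts sum
exactly to the total.

**Indirect costs** are productivity losses valued by the *friction cost
method*: output is lost only until the injured worker returns or is
replaced, so the observed lost workdays — not lifetime earnings — are
priced. With MLW the median lost workdays, NIE the number of injured
employees and MDWE the median daily wage,

$$AC = MLW \times NIE \times MDWE \times 1.28, \qquad
  PC = MLW \times NIE \times MDWE \times 1.5.$$

The absenteeism multiplier 1.28 is the median estimate of how much more a
day of missed work costs the firm than the wage itself (team disruption,
rescheduling, overtime); the presenteeism multiplier 1.5 prices the
sub-normal output of employees who attend while impaired. Both are
parameters of `friction_params()` and can be changed. Two modelling choices
deserve note:

* *Shared MLW.* No separate presenteeism duration is observed in claims
  data, so `mlw_present` defaults to `mlw_absent`. Supplying a distinct
  value is supported when presenteeism days are measured.
* *Friction period.* The observed lost workdays are treated as already
  friction-bounded — a compensation claim closes when the worker returns or
  is replaced. An optional `cap_days` argument truncates each absence at an
  explicit friction bound before the median is taken; the default is no
  cap.

**Totals and shares.** `build_summary()` adds the two components, computes
each component's percentage share, and converts to USD. A single exchange
rate (default 44.32 ETB/USD, the 2021 annual average of the Commercial Bank
of Ethiopia) is applied to *every* converted figure. Published cost tables
sometimes mix implicit rates across rows, which makes their USD columns
mutually inconsistent; we prefer internal consistency, so only figures
originally converted at the stated rate will be reproduced.

## Predictors of total cost: gamma GLM with log link

Per-claim total cost is positive and right-skewed, so predictors of cost
are modelled by a generalized linear model with a gamma family and log
link: $\log E[y_i] = x_i^\top \beta$, with the binary covariates long-term
absence (> 5 lost workdays), injury severity, unsafe act, sleeping
disorder, co-morbidity and inconsistent PPE use. Exponentiated coefficients
$e^{\beta_j}$ are **multiplicative effects on mean cost** — a claim with
the covariate costs $e^{\beta_j}$ times as much, other covariates equal.
(They are sometimes mislabelled odds ratios; a gamma/log model has no odds
scale, so this package does not use that term.) The response is modelled on
its raw scale through the log link; no log transformation of the data is
applied, and non-positive responses are a hard error rather than being
epsilon-shifted, since they lie outside the gamma support.

### Numerical choices

* **IRLS.** For the log link the gamma working weights are identically one
  ($(\partial\mu/\partial\eta)^2 / V(\mu) = \mu^2/\mu^2$), so each
  iteration is an ordinary least-squares solve of the working response
  $\eta + (y - \mu)/\mu$ against the design, via a QR decomposition
  computed once. Starting values come from OLS on $\log y$, which is
  already close to the optimum for these models.
* **Convergence** is declared when the relative deviance change falls
  below `1e-8`, with a cap of 100 iterations; non-convergence is recorded
  in the fit object and warned about, never silent. On well-conditioned
  designs convergence takes under ten iterations.
* **Dispersion** is estimated by Pearson's chi-square over residual degrees
  of freedom, the conventional moment estimator for gamma GLMs.
* **Confidence intervals** are Wald intervals on the log scale,
  $\exp(\hat\beta \pm 1.959964\,\widehat{se})$, with standard errors from
  the inverse Fisher information scaled by the estimated dispersion.
* Goodness of fit is summarised by deviance and Pearson statistics. The
  Hosmer–Lemeshow test is deliberately not offered: its grouping logic is
  defined for binary outcomes and has no accepted analogue for a gamma
  response.

Pre-modelling screens mirror standard practice: `vif()` flags variance
inflation factors above 10 (tolerance below 0.1), `correlation_screen()`
flags pairwise $|r| > 0.8$, and `normality_check()` reports adjusted
Fisher–Pearson skewness and the one-sample Kolmogorov–Smirnov statistic on
the raw and log scales — the diagnostics that motivate a skew-robust model
in the first place.

## The synthetic cohort generator

The compensation registry underlying the published analysis is not
publicly deposited, so `generate_cohort()` produces seeded synthetic
cohorts that emulate its *printed marginal structure*; every downstream
stage of the package is exercised against them. With defaults
(`sim_config()`):

* n = 1200 claims over calendar year 2021; categorical frequencies follow
  the published tables (disability classes 39.7 / 50.6 / 5.8 / 3.9 %, sex
  97.9 % male, nine body-part and eleven cause categories, injury timing
  36.44 / 20.69 / 42.87 %). One published body-part count exceeds the
  cohort size and is clearly a typo; its printed percentage (17.3 %,
  i.e. 208 claims) is used instead.
* Lost workdays come from a three-component mixture matching the reported
  absence bins (4 % under 5 days, 74.5 % at 5–30, 21.5 % over 30): uniform
  on 0–4; a discretised log-normal truncated to 5–30 whose location is
  solved numerically so the *overall* median equals 21.48 days; and a
  shifted truncated log-normal on 31–365. The registry reports only the
  median and bin masses, so the log-normal family is a choice — made to
  keep the right skew that cost data display.
* Daily wages are log-normal with median 207.6 ETB and `sdlog` 0.28,
  implying a standard deviation close to the reported 60.7 ETB.
* Medical costs are log-normal with median 3000 ETB. Per-class
  compensation is log-normal with class medians proportional to the
  published class totals per claim, rescaled by a common factor solved so
  the cohort-wide compensation median is 3426.32 ETB (class medians
  themselves are not published, so this calibration is deliberately loose;
  only the overall median is targeted).
* Per-claim total cost is $\mathrm{Gamma}(k, \mu_i/k)$ with $k = 2$
  (dispersion is not reported; $k=2$ gives pronounced but not extreme
  skew) and $\log \mu_i = \beta_0 + \sum_j \beta_j x_{ij}$ over five
  covariates with the published multiplicative effects as defaults
  (0.85, 1.11, 1.44, 0.90, 0.85). The intercept is solved so that the
  marginal mean cost equals the published grand total per claim
  (18 823.03 ETB) at the generator's own covariate prevalences — using the
  workday model's implied long-term-absence rate, since the published
  clinical table and the absence-bin counts are not mutually consistent.
* Covariates are drawn independently at the published prevalences; the
  registry reports no joint distribution. An equicorrelated Gaussian
  copula (`covariate_correlation`) is available for sensitivity work but
  off by default.

All randomness flows through a single seed; identical configurations give
byte-identical CSV output. Monetary values are rounded to cents at
generation so cohorts survive CSV round trips exactly.

**What passing tests do and do not show.** Because the generator matches
marginals only, agreement of the pipeline on synthetic cohorts
demonstrates the *arithmetic and statistical machinery* — not that the
real registry's joint structure is captured. In particular the regression
point estimates of the original analysis cannot be reproduced without the
raw records; what the test suite verifies instead is that (i) the IRLS
fitter agrees with a brute-force likelihood grid and an independent
reference implementation, and (ii) in a 200-replicate parameter-recovery
study at n = 1200 with the published effect sizes, each true effect is
covered by its 95 % Wald interval at the nominal rate (within ±3
percentage points). Those problem sizes keep the whole study to roughly a
minute on one CPU while leaving the binomial noise of the coverage
estimate (≈1.5 points) well inside the asserted band.

## Other conventions and edge cases

* Medians use the mean-of-middle-two convention for even n; workday bins
  are `[0,5)`, `[5,30]`, `(30,∞)` — the only partition under which the
  published bin counts sum to the cohort size; long-term absence is
  *strictly* more than 5 days.
* Percentages display half-up to 1 decimal (frequency tables) or 2
  decimals (cost shares); money displays half-up to cents. All arithmetic
  is full precision internally; `round_half_up()` exists because base R
  rounds half-to-even, which disagrees with how such tables are printed.
  Comparisons against published figures use an absolute 0.02 ETB
  tolerance, since published tables truncate or round inconsistently in
  the second decimal.
* The sample-size helper implements
  $n = \lceil \mathrm{deff} \cdot z^2 p(1-p)/d^2 \rceil$. Note that with
  the published inputs (p = 0.783, d = 0.05, deff = 1.5) it yields 392,
  not the 1136 reported alongside them; the formula's result is returned
  as computed.
* Cohort validation rejects rows violating field invariants with
  row-indexed diagnostics and drops (while counting) records with missing
  sex — or missing age when an age column is supplied; age feeds no other
  computation.

## Limitations

Only employer-side medical, compensation and productivity-loss components
are covered — no occupational disease, no replacement-hiring or training
costs, no human-capital alternative to the friction method, no societal or
worker perspective, and no inflation adjustment or multi-year projection.
The synthetic generator reproduces printed marginals, not the registry's
joint distribution, and its distributional families beyond those marginals
are modelling choices.
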