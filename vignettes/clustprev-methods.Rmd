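---
title: "Models and methods behind clustprev"
author: "clustprev authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clustprev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustprev)
```

## The problem

Population-based prevalence surveys for conditions such as epilepsy screen
whole communities through household visits.  The resulting data are
hierarchical three times over: individuals share households, households are
screened by one field interviewer, and interviewers work within one
geographic site.  Individuals who share any of these clusters tend to give
correlated answers — through shared environment and genetics (household),
through how a given interviewer administers the screening questions
(interviewer), and through site-level living conditions.  Treating such data
as independent Bernoulli draws underestimates the standard error of the
prevalence estimate; ignoring attrition between survey stages biases the
estimate itself.  `clustprev` implements the full analysis pipeline —
multilevel model, intraclass correlations, attrition simulation and
imputation — together with a synthetic-data generator, so every claim about
the pipeline can be tested without access to restricted survey data.

## The model

For individual $k$ in household $h$, screened by interviewer $j$ of site
$i$, the outcome is Bernoulli with

$$\pi = \operatorname{logit}^{-1}(\beta_0 + u_i + v_{ij} + w_h),
\qquad u_i \sim N(0, \sigma_u^2),\;
v_{ij} \sim N(0, \sigma_v^2),\;
w_h \sim N(0, \sigma_w^2),$$

all random intercepts independent, no covariates (the survey estimand is a
single prevalence).  The marginal likelihood integrates the random effects
out level by level, innermost first: households within interviewer,
interviewers within site.

Two prevalence estimands are exposed by `adjusted_prevalence()`:

* **population-averaged** (default):
  $\hat\theta = 1000 \int \operatorname{logit}^{-1}(\hat\beta_0 + z)\,
  \phi(z; 0, \hat\sigma_u^2 + \hat\sigma_v^2 + \hat\sigma_w^2)\,dz$,
  the marginal event rate of the fitted model.  Its 95% interval maps
  $\hat\beta_0 \mp 1.96\,\mathrm{se}(\hat\beta_0)$ through the same
  transform, so it inherits the (possibly large) cluster-level uncertainty
  of the intercept.
* **conditional**: $1000\,\operatorname{logit}^{-1}(\hat\beta_0)$, the rate
  of a cluster whose random effects are all zero.  For a rare outcome this
  is smaller than the population-averaged rate (Jensen's inequality); both
  outputs carry an estimand label so the two are never silently mixed.

Intraclass correlations use the latent-threshold convention for logistic
models: the individual-level residual variance is fixed at $\pi^2/3$, and

$$\mathrm{ICC}_\ell = \frac{\sigma_\ell^2}
 {\sigma_u^2 + \sigma_v^2 + \sigma_w^2 + \pi^2/3}.$$

This convention is the only one under which a variance decomposition of a
Bernoulli outcome yields ICCs strictly inside $[0, 1)$; a decomposition
without a residual term would force every model's ICCs to sum to one.  The
*cumulative* ICC — summed cluster variances over the total — is the
correlation between two individuals who share all modelled clusters, and it
is the quantity that grows as levels are added to a hierarchical model
(e.g. from roughly 0.10 for a site + interviewer model to roughly 0.41 when
the household level joins, under this package's calibrated preset).

## Fitting: why not a plain Laplace approximation

`fit_glmm()` maximizes the marginal likelihood itself, exploiting a
structural fact of the intercept-only model: all individuals of a cluster at
the innermost modelled level share one success probability, so a cluster of
size $m$ with $c$ cases enters the likelihood only through $(m, c)$.  The
data collapse to a few hundred (size, cases, upper-cluster) patterns
regardless of census size, which makes high-accuracy quadrature essentially
free.

The default `"laplace"` method is a hybrid:

* **household level** — adaptive Gauss–Hermite quadrature (default 15
  nodes, recentred at each pattern's conditional mode and rescaled by its
  curvature).  This level is where a joint Laplace approximation is
  untrustworthy: with a rare outcome and households of 1–15 members the
  integrand per household is far from Gaussian, the textbook setting in
  which Laplace variance-component estimates for binary data break down.
  The shipped oracle (`loglik_oracle()`) and the `"agq"` method make the
  comparison easy to run on any fixture; off-the-shelf fitters that
  default to joint Laplace inherit the same weakness at these data
  conditions.
* **site and interviewer levels** — Laplace approximation over the joint
  conditional mode, with the intercept profiled into the same Newton solve
  (the dependence of the Laplace determinant on $\beta_0$ is ignored during
  profiling and corrected by a final one-dimensional polish).  These
  clusters hold hundreds to tens of thousands of individuals each, so their
  conditional posteriors are very close to Gaussian and Laplace is
  accurate, and the approximation error is close to constant in the
  parameters, which is what parameter estimation needs.

The `"agq"` method instead applies nested adaptive Gauss–Hermite quadrature
at *every* level.  It is exact up to quadrature error for any cluster size
and is the method used for accuracy checks against the package's independent
dense-trapezoid oracle (`loglik_oracle()`); its cost grows quickly with the
number of upper-level clusters, so it is intended for small-to-moderate
data.

Numerical choices, all visible in `model_spec()`:

* Variance parameters are optimized on the log-SD scale (non-negativity by
  construction); a fitted log-SD below $-6$ is reported as a variance of 0
  with a boundary flag.
* Starting values: intercept from the crude logit, every SD at 0.3, with
  the innermost SD pre-refined by a cheap one-dimensional profile fit of
  that level alone.
* The outer optimizer is a Nelder–Mead simplex (restarted until it stops
  improving) rather than a finite-difference quasi-Newton method: the
  warm-started inner solves leave the objective smooth only down to about
  $10^{-5}$, which derails numerical gradients but is far below what the
  simplex needs — the same reason established mixed-model fitters default
  to derivative-free outer optimization.
* The inner Newton solves run to a gradient norm of
  $\max(10^{-6}|\ell|, 10^{-5})$; the implied objective noise is
  $O(\text{grad}^2/\text{curvature})$, orders of magnitude below the outer
  tolerances.
* `se(beta0)` comes from a central-finite-difference observed-information
  matrix over the intercept and all non-boundary log-SDs (step 0.05, chosen
  to sit well above the objective's noise floor while keeping truncation
  error in the percent range).

Likelihood-ratio tests between nested structures use the naive chi-square
reference with a boundary flag: variance components sit on the boundary of
their space under the null, so the reported p-values are conservative; no
mixture-of-chi-squares correction is applied.

## The synthetic census

`preset_survey_config()` builds the study conditions: 2 sites, 12 + 8 villages,
18 + 12 interviewers, households of 1–15 members drawn from truncated
geometric distributions with site-specific means (2.2 in the mobile
industrial-area site, 3.5 in the established site), roughly 55,000
individuals.  The three variance components are *solved* so the latent ICCs
equal 0.397 (household), 0.101 (interviewer) and 0.070 (site), and the
intercept is solved by quadrature so the marginal rate is 9.4 per 1,000;
nothing in the preset hard-codes an estimate as a truth, so changing the
targets re-derives a consistent preset.

Design choices where the real survey's protocol is not public:

* Interviewers receive contiguous blocks of the village-ordered household
  list within their site (seeded random cut points).  This reduces to
  whole-village assignments when interviewers are fewer than villages and
  otherwise splits villages at block boundaries, giving interviewer
  workloads that partially align with villages — the structure that makes
  the interviewer and village levels distinguishable but correlated.
* All randomness flows from one integer seed through a documented
  substream-splitting scheme (structure, random effects and outcomes each
  use their own substream), which is what makes every stage byte-reproducible.

What the generator deliberately does *not* emulate: covariate effects
(the linear predictor carries no $X\beta$ term), the two-stage
screen-then-confirm cascade as separate error processes, spatial
coordinates, and any informative relationship between household size and
the outcome.  Passing tests therefore demonstrate correct behaviour of the
*estimators* under the stated generative model, not robustness to
measurement error or informative cluster sizes in real surveys.

A consequence worth stating plainly: with only **two** site clusters, the
site-level variance is weakly identified no matter how many individuals are
surveyed.  Maximum likelihood shrinks $\hat\sigma_u^2$ toward zero (one
effective degree of freedom, partly absorbed by the intercept) and the 30
interviewer effects can mimic almost any realized site contrast at small
prior cost.  The shipped replicated recovery study shows exactly this: the mean
estimated site ICC falls well below its generating value of 0.070 while the
household and interviewer ICCs recover within a few hundredths.  This is a property
of the survey design itself, not of the estimator: any analysis of a
two-site survey should treat the site-level variance estimate (and the
paper-style site ICC) as essentially unidentified.  The package reports it
anyway, with the boundary flag where relevant.

## Attrition

`apply_attrition()` blanks outcomes independently with probabilities from a
logistic dropout model whose intercept is solved by bisection so the mean
dropout probability equals the target rate (10% and 20% in the standard
experiment).  The mechanism is missing-at-random by construction: dropout
may depend on site, household size, interviewer sex and — through the
`village_coef` channel — the *leave-one-out* village event rate, but never
on the record's own outcome.  The village channel exists because, with only
two sites, site-level dropout alone produces a complete-case bias too small
to measure; tilting dropout toward high-prevalence villages reproduces the
qualitatively important phenomenon that unaddressed attrition biases
prevalence downward, while remaining MAR with respect to the value that
goes missing.

## Sequential KNN imputation

Missing outcomes are filled in a deterministic order (records whose
household retains the most observed members first, so the best-informed
cells become donors early), each from its $k$ nearest donors under a
Gower-type distance over cluster co-membership indicators (household,
interviewer, village, site), household size and interviewer sex.  Two vote
rules are provided, because for a *rare binary* outcome they behave very
differently:

* **majority vote** is the accuracy-optimal point prediction — and for that
  very reason imputes almost no events: at a 1% event rate the majority of
  any donor set is virtually always 0.  Used where per-cell accuracy is the
  goal.
* **hot-deck** (default) copies one randomly drawn donor of the $k$
  nearest.  The imputed cells then reproduce the local event rate, which is
  what the prevalence and ICC analyses need.

Two pitfalls discovered while validating the hot-deck rule shaped the
defaults, and both are worth knowing about when configuring it:

* **Tied distances must be broken randomly per recipient.**  Whole village
  blocks share one covariate profile, so any fixed tie-breaking order
  recycles the same few donors for every recipient in a stratum, and the
  donor pool's sampling noise becomes a systematic prevalence bias of
  several per 1,000 in either direction.
* **Same-household donors must be a minority of the pool.**  Copying a
  household co-member into a household creates an artificial
  perfectly-concordant pair, inflating the household variance component;
  drawing only from distant donors dilutes genuine household concordance
  and deflates it.  The default pool size $k = 15$ balances the two
  effects at the default attrition levels (with the household co-membership
  weight dominant in the distance, a household typically contributes 1–3 of
  the 15 donors); a small $k$ with household-dominant weights measurably
  inflates the household ICC.

`imputation_quality()` scores a completion against the pre-attrition truth
(cell accuracy, prevalence error, and per-level ICC shift under a chosen
model structure).

## The experiment grid

`run_grid()` crosses attrition level $\times$ clustering structure
$\times$ missing-data handling over replicates, one census per grid (or
fresh per replicate on request), and emits a flat results table: prevalence
per 1,000 with its interval, per-level variances and ICCs, cumulative ICC,
log-likelihood, AIC/BIC and convergence per cell.  Failed cells are
recorded as non-converged rows, never dropped.  `compare_models()` ranks
structures by AIC with BIC as tie-break.  Under the calibrated preset the
random-effects structures dominate the fixed-intercept model, interval
widths grow with the cumulative ICC, complete-case prevalence falls as
prevalence-correlated attrition rises, and the hot-deck completion pulls
the estimate back toward the full-data value.

## Problem sizes used by the test suite

The shipped tests run the replicated studies at sizes chosen to make their
Monte-Carlo error small relative to the assertions: 100 preset censuses
(about 55,000 individuals each) for ICC recovery and model selection; 1,000
replicates of a 12-site, ~1,500-individual design for interval coverage
(where a well-identified many-cluster design is deliberately used — the
two-site preset cannot support coverage statements about site-level
uncertainty); and a dozen attrition re-draws on one fixed preset census for
the attrition/imputation claims, mirroring a survey where the census is
fixed and only the missingness mechanism is stochastic.

## Known limitations

* No covariates: the package estimates a single prevalence, as in the
  analysis it implements; extending the collapsing trick to covariate
  models would break the sufficient-statistic reduction.
* The population-averaged interval transforms only the intercept's
  uncertainty; variance-component uncertainty is not propagated (no
  profile or bootstrap intervals for ICCs, which the reference analysis
  also does not report).
* Laplace accuracy at the upper levels relies on large clusters; for
  designs with many *small* interviewer clusters prefer `method = "agq"`.
* Single imputation only: between-imputation variance is not pooled, so
  post-imputation standard errors are mildly optimistic.
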