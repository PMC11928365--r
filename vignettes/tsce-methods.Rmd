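---
title: "Methods: the two-stage clonal expansion model of lung cancer incidence"
author: "tsce package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-stage clonal expansion model of lung cancer incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsce)
```

## The model

The two-stage clonal expansion (TSCE) model describes carcinogenesis as
initiation, promotion and malignant conversion.  A pool of `X` normal stem
cells acquires a first ("initiating") alteration at rate `mu0` per cell-year,
so initiated cells arise as a Poisson process with total intensity
`nu = X * mu0`.  Each initiated cell founds a clone that undergoes a
stochastic birth-death process: division at rate `alpha`, death/differentiation
at rate `beta`.  Any initiated cell can convert to a malignant cell at rate
`mu1`; the appearance of the first malignant cell is identified with cancer
occurrence (an optional fixed diagnosis lag, default 0, can shift the curve
in age).  The net clonal growth rate — *promotion* — is the quantity cohort
data identify well:

    g = alpha - beta - mu1

Time is age in years; all rates are per year (per cell-year for `mu0`,
`mu1`).  Following the convention used in cohort analyses of lung cancer,
`X = 1e7` and `alpha = 3` are fixed (they are not separately identifiable
from incidence data), `mu0 = mu1` is enforced, and `beta` is always derived
as `alpha - g_eff - mu1_eff`, never estimated directly.  Because `g` is
defined net of conversion, we subtract the *dose-modified* `mu1` when
deriving `beta`; at zero dose, where `mu0 = mu1`, this is numerically
indistinguishable from subtracting the background value, and at realistic
doses the difference is of order `1e-6` per year.  The derivation errors out
if `beta` would go negative at any dose used.

## Smoking dose response

Individual smoking is a piecewise-constant trajectory of cigarettes per day
(CPD) reconstructed from questionnaire fields: age started, CPD (categorical
answers are converted to interval means: 8, 15.5, 25.5 for the bounded
categories, with configurable 3.5 and 40 for the open-ended "<=6" and
">=31"), and age quit.  Dose modifies promotion and malignant conversion
multiplicatively:

    theta_tobacco = theta * (1 + theta_c * dose^theta_p)

with coefficient `theta_c` and power `theta_p` per mechanism.  Tumour
initiation is left unmodified by default (cohort fits do not support a
smoking effect on initiation; the package still offers an optional
initiation coefficient for model comparison).  The promotion power
`g_p = 0.4013` is shared across groups and the conversion power
`mu1_p = 0.4684` is fixed to a previously published two-cohort estimate;
both are overridable in `tsce_spec()`.  Dose changes between questionnaires
take effect at the reporting assessment age, with no interpolation — the
data give no basis for ramping.  Because smoking assessments end, follow-up
is censored a fixed window (default 10 years, with 5/15/30 used for
sensitivity analysis) after the last assessment; a case diagnosed after the
censoring age becomes a non-case exiting at that age.

## Exact survival and hazard

For piecewise-constant rates the filtered process (no malignant cell by age
`t`) admits an exact solution.  Let `Gamma(u; t)` be the probability that a
clone founded by one initiated cell at age `u` produces no malignant cell by
`t`.  It satisfies the backward Riccati equation

    dGamma/du = (alpha + beta + mu1) Gamma - alpha Gamma^2 - beta,
    Gamma(t; t) = 1,

whose right side factors through the roots `y±` of
`alpha y^2 - (alpha+beta+mu1) y + beta`, with `y- < 1 < y+`.  The Möbius
transform `w = (Gamma - y+)/(Gamma - y-)` then propagates exponentially
within an interval, `w(u) = w(r) exp(s (r - u))` with
`s = sqrt((alpha+beta+mu1)^2 - 4 alpha beta)`, and terminal conditions chain
backward across breakpoints.  Survival and hazard follow from

    S(t) = exp(-Int_0^t nu(u) (1 - Gamma(u; t)) du),
    h(t) = Int_0^t nu(u) B(u; t) du,

where `B = -dGamma/dt` satisfies a linear backward equation with
`B(t; t) = mu1(t)` and is proportional to `(Gamma - y+)(Gamma - y-)` within
an interval, so both integrals have closed forms — no quadrature is needed.

Numerical policy: all propagation is done in the shifted variables
`Gamma - 1`, `1 - y+` and `1 - y-`, computed by stable formulas
(`1 - y± = (alpha - beta - mu1 ∓ s)/(2 alpha)`), because at the parameter
magnitudes of lung cancer (`mu1 ~ 1e-7`) the raw quantities agree to seven
digits and naive subtraction would destroy precision.  The log-survival is
accumulated directly (no exponential until requested), which is also what
the likelihood consumes.  The degenerate double-root case (`mu1 = 0` with
`alpha = beta`) has its own branch.  An independent check,
`tsce_ode()`, integrates the same backward equations numerically with
`deSolve::lsoda` at relative tolerance `1e-10`; the test suite holds the two
routes to within `1e-6` relative on randomized schedules, and a direct
branching-process Monte Carlo (`branching_survival()`) confirms `1 - S(t)`
at the cell level on a fast-parameter toy.

## Likelihood, fitting and model selection

Each individual contributes a left-truncated term conditional on being
cancer-free at study entry `ae`: cases contribute
`log f(al) - log S(ae)` at the exit age `al`, non-cases
`log S(al) - log S(ae)`; deaths and administrative end of follow-up are
non-case exits (no competing-risk decomposition).  The cohort log-likelihood
is the sum over individuals, with one parameter set per
race/ethnicity-gender group.

`tsce_fit()` maximises the likelihood by BFGS on log-transformed parameters
(a natural-scale option with per-parameter scaling exists and reaches the
same optimum; the log scale is the default because all free parameters are
positive rates spanning six orders of magnitude).  Multistart (default 5)
jitters the starting magnitudes by a factor uniform in \[0.5, 1.5\] of the
log scale around defaults of the fitted order of magnitude
(`mu0 = 3e-7`, `g = 0.05`, coefficients 0.3) and returns the best optimum;
the jitter is seed-controlled.  Free parameters can be shared, race-,
gender- or group-specific (`tsce_spec()`), nested models are compared by
likelihood-ratio tests and non-nested ones by AIC (`lrt()`,
`select_models()`).  The LRT guard against failed optimisation allows
numerical slack of `1e-6 |loglik|`: when a coefficient's true value sits on
the `0` boundary the log-scale optimiser can leave the full model a hair
below its restriction, which is a boundary artifact, not a failure.

Uncertainty is by random-walk Metropolis-Hastings (`tsce_mcmc()`) on log
parameters with a flat prior on the natural-scale domain (the log-Jacobian
is included so the target is the likelihood in natural parameters); the
proposal shape comes from the inverse Hessian at the optimum and the global
scale adapts during burn-in (default 20% of the chain) towards 20-40%
acceptance.  Reported intervals are equal-tailed percentile intervals of
the post-burn-in draws — the only reading of "MCMC confidence intervals"
consistent with a Metropolis-Hastings procedure.  Hessian-based standard
errors are shown by `summary()` as a diagnostic only.

## The synthetic cohort generator

Real multiethnic-cohort records are access-restricted, so the generator
(`simulate_cohort()`) emulates the published composition of the analysis
sample and draws outcomes from the TSCE model itself, making every stage of
the pipeline testable end to end.  Published structure used as defaults:
group sizes (33,067 / 48,519), female fractions (63.8% / 53.9%), entry ages
truncated-normal on \[45, 76\] with means 61.8 / 59.5 (SD 9.08; the location
parameter is calibrated so the *truncated* mean matches the published mean),
never/former/current mixes 39.0/38.0/22.7% and 39.2/43.8/16.7%
(renormalised after dropping the small "missing" share), administrative
follow-up capped at 24.7 years, a baseline smoking assessment at entry with
follow-up questionnaires offered 10 and 15 years later, and 10-year
post-assessment censoring.

Quantities the published tables do not report are fixture choices, made
once and documented rather than tuned: initiation ages truncated-normal
(17.5, SD 4) on \[10, 35\]; CPD-category probabilities
(0.15, 0.30, 0.35, 0.12, 0.08) over the five categories; former smokers'
quit ages uniform between initiation + 1 and entry (first-questionnaire
smoking history predates entry); questionnaire participation 0.7 and 0.6.
These are not estimates of the real cohort's joint distribution.

Event ages are drawn exactly from each individual's own model: given
uniform `U`, the event age solves `S(T)/S(ae) = U` by bisection on the
closed-form log-survival, conditional on entry (`T > ae`), mirroring the
left truncation in the likelihood; `is_case = (T <= exit)`.

What the generator deliberately omits — and hence what passing tests do and
do not show about real data: there is no other-cause mortality (follow-up
truncation and assessment censoring stand in for it; the likelihood treats
deaths as censoring anyway), so the synthetic case fraction (~10% in the
male-only recovery cohorts) exceeds the published ~3-3.5%, which makes the
recovery studies slightly *better* identified than the real analysis; there
is no reporting error or within-person dose variability beyond the
questionnaire breakpoints; smoking behaviour never changes after entry
except via the recorded quit age; and the joint age-smoking-gender
distribution matches the published marginals only.

## Simulation-study sizes and tolerances

The package's own validation studies use: parameter recovery at
n = 50,000 per group over 5 seeds (median recovered `mu0` and `g` within
15% of truth, tobacco coefficients within 20% — those are less well
identified); 95% interval coverage of `mu0` in at least 18 of 20 replicates
at n = 50,000 with 5,000-step chains; solver-oracle agreement at `1e-6`
relative over 100 random schedules; refinement invariance at `1e-10`;
conservation identities at `1e-8`; and a `1e5`-run branching-process check
within three binomial standard errors.  Unit tests use smaller cohorts
(2,000-25,000) with correspondingly looser, property-level assertions.
All stochastic tests fix their seeds, so outcomes are reproducible
deterministic checks rather than flaky draws.

## Known limitations

Only the two analysed race/ethnicity groups are parameterised; other tobacco
products, menthol, inhalation depth and pack-year-based modelling are out of
scope (the model consumes CPD trajectories; pack-years appear only as a
descriptive statistic).  The hazard treats the first malignant cell as
incidence; tumour growth, sojourn time and screening are not modelled.
The generator's omissions listed above mean quantitative agreement with any
real cohort's absolute case counts is not expected, only the structure of
the inference problem.
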