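# tsce

Two-stage clonal expansion (TSCE) models of lung cancer incidence under
individual, time-varying smoking exposure.

Lung cancer incidence differs strikingly by race/ethnicity in ways crude
smoking summaries do not explain: non-Hispanic Black (NHB) men smoke fewer
cigarettes per day than non-Hispanic White (NHW) men yet have higher
incidence.  Multistage carcinogenesis models separate that risk into
mechanistic pieces — background and smoking-related tumour **initiation**,
clonal **promotion**, and **malignant conversion** — each with its own age
and dose dynamics.  This package is for epidemiologists and cancer modellers
who want to fit, test and simulate such models on cohort data (or, absent
access to restricted cohort records, on faithful synthetic cohorts).

## The model

`X = 1e7` stem cells are initiated at rate `mu0` per cell-year; initiated
cells divide at `alpha = 3`, die at `beta`, and convert to malignancy at
`mu1` per cell-year; the first malignant cell is cancer occurrence.  The
identifiable promotion rate is `g = alpha - beta - mu1`.  A piecewise
cigarettes-per-day trajectory `d(t)`, reconstructed from questionnaire
records, acts multiplicatively on promotion and malignant conversion:

    theta_tobacco(t) = theta * (1 + theta_c * d(t)^theta_p)

Survival `S(t)` and hazard `h(t)` of the filtered process are computed
exactly per dose interval via the factored backward Riccati equation (no
quadrature).  Individuals enter the cohort cancer-free at age `ae` and exit
at `al`, so a case contributes `log f(al) - log S(ae)` and a censored exit
`log S(al) - log S(ae)`; the cohort log-likelihood is maximised by BFGS on
log parameters with group-structured sharing (`mu0 = mu1`, `g`, `g_c`,
`mu1_c` free per race-gender group by default; `X`, `alpha` and the
dose-response powers fixed).  Intervals come from random-walk
Metropolis-Hastings on the likelihood surface.

## Worked example

```r
library(tsce)

# a synthetic NHB-male cohort generated from the fitted reference parameters
cfg <- cohort_config(races = "NHB", n = c(NHB = 20000),
                     female_fraction = c(NHB = 0))
coh <- simulate_cohort(cfg, seed = 1)
table(coh$is_case)
#> FALSE  TRUE
#> 17797  2203

fit <- tsce_fit(coh, tsce_spec(), starts = 3, seed = 1)
fit
#> TSCE model fit (20000 individuals, 2203 cases, 1 group)
#> log-likelihood -11576.028 on 4 free parameters; AIC 23160.057
#> coefficients:
#>   mu0[NHB.male]     g[NHB.male]   g_c[NHB.male] mu1_c[NHB.male]
#>       4.247e-07       4.458e-02       3.344e-01       4.183e-01
```

The generating truth was `mu0 = 4.058e-7`, `g = 0.0454`, `g_c = 0.3306`,
`mu1_c = 0.4160`: all four are recovered within ~5% at this cohort size.
Percentile intervals and scenario curves:

```r
percentile_ci(tsce_mcmc(fit, n_steps = 5000, seed = 1))
#>                        lo        hi
#> mu0[NHB.male]   3.537e-07 5.326e-07
#> g[NHB.male]     3.726e-02 5.040e-02
#> g_c[NHB.male]   2.845e-01 4.154e-01
#> mu1_c[NHB.male] 3.062e-01 5.412e-01

p <- reference_params("NHB", "male")
relative_risk(p, tsce_scenario("current", cpd = 20, start_age = 20),
              tsce_scenario("never"), ages = c(50, 70, 90, 100))
#>   age         hA        hB       rr
#> 1  50   321.5319  31.37762 10.24717
#> 2  70  1915.5182  82.52531 23.21128
#> 3  90  6976.3083 205.85170 33.88997
#> 4 100  9721.7223 320.04768 30.37586
```

Hazards are per 100,000 person-years.  The smoker-vs-never relative risk
rises while smoking duration accumulates (peaking near age 90 for this
group) and then declines as never-smoker background risk catches up — the
characteristic TSCE signature.  `run_pipeline()` chains
simulate → fit → select → MCMC → report into an artifact directory.

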