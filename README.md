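# etiohet

Diagnostics for **age-related etiologic heterogeneity** in prospective
cohort time-to-event data — that is, for covariate effects that change
with the age at which a disease process begins, which under a Cox model
appear as violations of the proportional hazards (PH) assumption.

The motivating setting is cohorts of children at increased genetic risk
of type 1 diabetes followed from early life for the onset of islet
autoimmunity: subjects enter between birth and age 8, are tested at 9,
15, and 24 months and then annually, the event age is the first positive
visit, censoring is the last negative visit, and children already
positive at their first visit are left-censored and excluded. A risk
factor that acts only in infancy (or only in adolescence) can average
out to "no association" in a standard Cox fit; these tools are for
finding and modelling exactly that.

## What it computes

For the hazard model `h(t|x) = h0(t) exp(beta(t) x(t))` on
counting-process episodes `(start, stop]` (delayed entry and
time-varying covariates supported throughout):

* **Supremum test** (`supremum_test`): the largest excursion of the
  observed standardized cumulative score process is compared with 1,000
  multiplier-resampled null paths; the p-value is the exceedance
  fraction. Deterministic given the seed, which is recorded in the
  result.
* **Scaled Schoenfeld residuals** (`zph_test`, `smooth_beta_t`): the
  Grambsch–Therneau score test for a zero slope of the scaled residuals
  on transformed event time (per covariate, df 1, and global), plus a
  local-linear smooth of `beta(t)` with a ±2 SE band.
* **Restricted cubic splines** (`fit_rcs_cox`, `hierarchical_tests`,
  `hr_curve`): `beta(t)` expanded in a k-knot RCS basis (knots at the
  5th/50th/95th percentiles of event ages for k = 3; AIC selection via
  `select_knots_by_aic`), with hierarchical Wald tests — association
  (df k), nonconstancy (df k−1, the PH violation test), nonlinearity
  (df k−2) — and `HR(t) = exp(delta * beta(t))` curves with pointwise
  95% bands. Works for time-varying covariates via episode expansion.
* **Cohort simulator** (`scenario`, `simulate_cohort`, `power_study`):
  visit-based prospective cohorts with staggered entry, piecewise
  constant baseline hazard, detection-time events, left-censoring, and
  named effect shapes (`"null"`, `"nhw-like"`, `"maternal-age-like"`,
  `"n3fa-like"`).
* **Consolidated report** (`run_assessment`, `cli_main`): all
  diagnostics per covariate in one table/JSON, with N/A cells carrying
  machine-readable reasons (hierarchy gating; diagnostics not applicable
  to time-varying covariates).

## Worked example

```r
library(etiohet)

sc  <- default_scenario("nhw-like", n_subjects = 1000)  # HR > 1 early, < 1 late
sim <- simulate_cohort(sc, seed = 11)
ex  <- exclude_left_censored(sim$subjects)
ep  <- expand_counting_process(ex$retained)

fit <- fit_cox(ep, "nhw")
supremum_test(fit, "nhw", seed = 1)
#> Supremum test of proportional hazards for 'nhw'
#>   observed sup |W| = 0.3215 over 231 events
#>   p-value = 0.034 (1000 resampled paths, seed 1)
zph_test(fit)
#> Scaled Schoenfeld residual test of proportional hazards (transform: km)
#>         chisq df     p
#> nhw    9.5235  1 0.002
#> GLOBAL 9.5235  1 0.002
rf <- fit_rcs_cox(ep, "nhw", k = 3)
hierarchical_tests(rf)
#> Hierarchical RCS tests for 'nhw' (gate alpha = 0.05)
#>   association  chisq = 8.966, df = 3, p = 0.02975
#>   nonconstant  chisq = 8.622, df = 2, p = 0.01342
#>   nonlinear    chisq = 0.4044, df = 1, p = 0.5248
hr_curve(rf, c(2, 11))
#>   age       beta        hr     lower    upper extrapolated
#> 1   2  0.8405913 2.3177370 1.2419431 4.325404        FALSE
#> 2  11 -0.3597528 0.6978488 0.4008864 1.214790        FALSE
```

The supremum p-value (0.034) and the scaled-Schoenfeld and nonconstancy
tests (p = 0.002 and 0.013) all flag the proportional-hazards violation
this scenario was built with: the covariate is a risk factor early
(HR 2.3 at age 2) and trends protective by age 11 (HR 0.70), while the
nonlinearity test (p = 0.52) finds no evidence that the decline deviates
from a straight line in age.

A command-line wrapper with `simulate`, `assess`, and `power`
subcommands is installed at `inst/exec/etiohet`:

```sh
Rscript inst/exec/etiohet simulate --scenario nhw-like --seed 7 --out-dir out/
Rscript inst/exec/etiohet assess --subjects out/subjects.csv \
    --covariate nhw --ages 2,11 --out report.json
```

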