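---
title: "Assessing age-related etiologic heterogeneity with etiohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing age-related etiologic heterogeneity with etiohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etiohet)
```

## The problem

Prospective cohorts of children at elevated risk of type 1 diabetes are
followed from early life for the onset of islet autoimmunity (IA): the
appearance of circulating autoantibodies against pancreatic beta cells,
detected at scheduled clinic visits. Risk-factor analyses of such cohorts
are usually Cox proportional hazards (PH) regressions, which assume a
covariate's hazard ratio is constant over age. When an exposure acts
mainly in a particular age window — *age-related etiologic
heterogeneity* — that assumption fails, the time-averaged hazard ratio
can sit near 1, and a real association may be missed entirely. Detecting
and modelling the violation is therefore not a nuisance check but the
scientific question itself.

`etiohet` implements three complementary assessments of nonproportional
hazards for delayed-entry (left-truncated), counting-process survival
data, together with a cohort simulator used as the test bed for all of
them.

## The model and the three diagnostics

All methods start from the hazard model

$$ h(t \mid x) = h_0(t)\, \exp\{\beta(t)\, x(t)\}, $$

where $t$ is age, $x(t)$ may be fixed or time-varying, and
proportionality means $\beta(t) \equiv \beta$. Fits are by the Cox
partial likelihood over risk sets $\{i : \mathrm{start}_i < t \le
\mathrm{stop}_i\}$, so staggered entry and episode-represented
time-varying covariates are handled by construction. Ties are handled by
Breslow's method by default (Efron selectable); Newton–Raphson with
step-halving stops when the largest score component falls below `1e-8`
(50 iterations maximum), and nonconvergence — including monotone
likelihoods from perfect separation — is reported as an error rather
than silently returned.

**Supremum test** (`supremum_test`). The observed cumulative sum of a
covariate's Schoenfeld residuals, standardized by $n^{-1/2}$, is a
tied-down, mean-zero process under PH. Its largest absolute excursion is
compared with the suprema of resampled null paths built by perturbing
each event's score contribution with independent standard-normal
multipliers and re-centering with the estimated information (the wild /
multiplier resampling of the standardized score process). The p-value is
the fraction of 1000 (by default) simulated suprema at or above the
observed supremum; the supremum uses the absolute value of the path, so
two-sided departures are detected. The seed is a required, recorded part
of the result: identical data, path count, and seed reproduce the result
bit for bit.

**Scaled Schoenfeld residuals** (`zph_test`, `smooth_beta_t`). Each
Schoenfeld residual row, scaled by (number of events) times the
coefficient covariance and offset by $\hat\beta$, approximates
$\beta(t)$ at that event time. The test is the exact score test for
adding $x \cdot g(t)$ to the fitted model: with the transform centered at
its event mean, the score of the added block is $u = \sum_j g_j r_j$ and
the statistic is $u^\top (I_{22} - I_{21} I_{11}^{-1} I_{12})^{-1} u$,
assembled from per-event-time information increments. The default
transform is `km` ($g(t) = 1 - S(t^-)$ from the overall Kaplan–Meier
curve), with identity, rank, and log selectable; the transform is
recorded in the output, and no claim of exact replication of any
particular published analysis is made. `smooth_beta_t` adds a local
*linear* loess smooth (default span 0.75 — the method literature names no
smoothing parameter, so a standard default is used) with a pointwise
$\pm 2$ SE band; local linear smoothing reproduces exactly linear
residual patterns exactly, which the tests exploit. For time-varying
covariates the scaling assumes a roughly constant risk-set variance; when
the empirical risk-set variance differs by more than a factor 4 (the
`var_ratio` argument) across event-time terciles, the result carries an
explicit reliability warning rather than a silent number.

**Restricted cubic splines** (`fit_rcs_cox`, `hierarchical_tests`,
`hr_curve`). $\beta(t)$ is expanded in a restricted cubic spline basis
with $k$ knots: $\beta(t) = \theta_0 + \theta_1 b_1(t) + \dots +
\theta_{k-1} b_{k-1}(t)$, where $b_1(t) = t$ and the $k-2$ remaining
terms are truncated-cubic combinations, linear beyond the boundary knots
and $C^2$ at the knots (Harrell form, scaled by the squared knot range
for conditioning; any fixed positive scale leaves the tests invariant).
Knots default to the 5th/50th/95th percentiles of the *event* ages
(linear-interpolation quantiles; censored ages excluded), keeping the
parameter count small when events are limited; `select_knots_by_aic`
compares $k = 3, 4, 5$ by AIC with ties broken toward fewer knots. Three
Wald tests are performed hierarchically: association (all $k$
interaction parameters; the constant $\theta_0$ is part of the
interaction block, which is what produces the $k$-df structure),
nonconstancy ($k-1$ time terms — the PH violation test), and nonlinearity
($k-2$ nonlinear terms); each later test runs only if the earlier null
was rejected at 0.05, with a switch (`gated = FALSE`) to compute all
three regardless, since marginal nonlinear p-values can still be of
interest. Tests are Wald-type, matching the macro family this
methodology descends from. `hr_curve` reports $HR(t) = \exp\{\delta\,
\hat\beta(t)\}$ for a user-chosen contrast $\delta$ (e.g. 5 years of
maternal age — rescaling the covariate or rescaling the contrast yield
identical curves, so $\delta$ is exposed explicitly) with a pointwise
delta-method band on the linear predictor. Grid ages outside follow-up
are linearly extrapolated (the spline's tail behaviour) and flagged with
a warning.

For a time-varying covariate, episodes are split at every distinct event
age, the basis is evaluated at the episode stop, and the covariate value
current at that age multiplies it — the natural counting-process
generalization of the fixed-covariate spline methodology. Output flags
this as an extension (`time_varying`); the supremum and
scaled-Schoenfeld diagnostics are reported as not applicable for such
covariates by default.

## The simulator: what it emulates, and what it does not

`scenario()`/`simulate_cohort()` emulate the design features that shape
such cohorts:

* staggered entry: 70% of subjects enter at birth, the rest uniformly
  between 0 and 8 years;
* a piecewise-constant baseline hazard, by default 0.05, 0.025, 0.04
  per year on [0, 2), [2, 6), [6, 15) — an early-incidence-peak shape
  sized so that moderate cohorts (n = 300) yield enough events (~60–80)
  for spline fitting; real IA incidence is far lower, and the published
  baseline shape is described only qualitatively, so these rates are
  deliberate test-bed stand-ins, not cohort estimates;
* scheduled visits at 0.75, 1.25, 2 years then annually; the *recorded*
  event age is the first visit at or after true onset (drawn by
  piecewise-exponential inversion on a 0.05-year grid), censoring is at
  the last attended visit, and onsets before the first attended visit
  are flagged positive-at-first-visit, reproducing the left-censoring
  filter pattern;
* exponential, covariate-independent dropout (0.05/year) and
  administrative follow-up to 12 years;
* late entrants take their first test at the first scheduled visit after
  entry (a simplification of "tested at enrollment" that keeps exit age
  strictly after entry age for every record).

Shipped effect shapes are anchored to published hazard-ratio endpoints
rather than to any cohort's raw data: `"nhw-like"` uses
$\beta(t) = 0.77 - 0.111\,t$ (HR 1.74 at age 2 declining through 1 to
0.64 at age 11); `"maternal-age-like"` a natural-spline $\beta(t)$
through (0, .15), (2, .131), (6, .02), (11, −.186) per 5-year unit;
`"n3fa-like"` a declining linear effect of a noisy subject-level exposure
trajectory; `"null"` sets $\beta \equiv 0$, the exact PH null even under
visit discretization, which is the clean condition for type-I-error
calibration.

What the simulator does **not** capture: interval censoring beyond the
first-positive-visit convention (event ages are treated as exact at the
detection visit), accelerated re-testing after a first positive result,
informative dropout, genetic risk stratification, case-cohort
subsampling, and measurement of multiple correlated exposures. Passing
calibration and recovery tests on these cohorts therefore demonstrates
correctness of the machinery under a realistic visit/truncation
structure, not validity of any substantive conclusion about real data.

## Numerical choices and degenerate inputs

* Episodes are half-open `(start, stop]`; the risk set at an event time
  `t` is `start < t <= stop`, and an episode whose boundary ties an
  event time is at risk per that rule. Splitting an episode at interior
  non-event times changes nothing (verified to 1e-8).
* Covariates are centered internally; estimates, residuals, and tests
  are invariant to location shifts and (for p-values) to rescaling.
* Martingale residuals use the Breslow baseline under both ties
  methods; they sum to zero exactly, as do Schoenfeld residual columns.
* Degenerate inputs error loudly: zero events, covariates with no
  contrast in any risk set, perfect separation (monotone likelihood),
  fewer than three events or a constant time transform in `zph_test`,
  duplicate spline knots from degenerate event-age distributions.
* AIC knot selection skips failing candidates and breaks exact ties
  toward fewer knots.

## Study sizes used by the test suite

The shipped tests are Monte-Carlo studies at fixed seeds: type-I-error
calibration uses the null scenario at n = 300 with 500 replicates
(observed rejection 0.03–0.05 for all three tests, inside the 95%
binomial envelope [0.031, 0.069]); power ordering compares the
sign-reversing scenario with the null at n = 500, 200 replicates; HR(t)
pattern recovery uses n = 1000, 200 replicates (the fitted curve is
above 1 at age 2 and below 1 at age 11 in ~85% of replicates); the
smoothed-residual slope-sign check runs at n = 800, where the sign is
recovered in effectively all replicates. Crossing-age recovery is
asserted as median-consistency against the detection-lag-adjusted
crossing (the generating effect crosses zero at 6.94 years on the onset
scale; annual-visit detection shifts the recorded-scale crossing by
about half a visit interval): with ~270 events the replicate-level
crossing estimate has a standard deviation near 1.6 years, so the
median, not each replicate, is the meaningful target.

## Known limitations

* The Wald hierarchy is asymptotic; with very few events (tens) the
  spline tests become conservative and knot placement unstable.
* The scaled-Schoenfeld test for time-varying covariates is reported
  with, at best, a variance-stability warning — it is not corrected.
* The supremum test for time-varying covariates is an extension beyond
  standard implementations and is flagged as such in its output.
* Case-cohort weighted estimation, competing risks, frailty, and formal
  interval-censoring likelihoods are out of scope.
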