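---
title: "Methods: empirical validation of patient safety indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical validation of patient safety indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Patient Safety Indicators (PSI) are screening measures of potentially
preventable in-hospital adverse events computed from routine discharge
abstracts. Before health authorities rank or flag hospitals with them,
three empirical questions need answers:

a. is the between-hospital variation in adjusted incidence *systematic*,
   or compatible with random (Poisson) noise?
b. does the indicator measure differences among *hospitals*, as opposed to
   differences among their patients (the cluster effect)?
c. can individual hospitals be flagged as significantly *above the
   expected* rate, given how rare these events are?

`psival` implements one self-contained pipeline per indicator —
risk adjustment, variation statistics, multilevel cluster metrics and
shrunken-residual profiling — together with a synthetic discharge-data
generator whose ground truth is recorded, so every estimator in the
package can be exercised against data whose answer is known.

# The models

## Risk adjustment and indirect standardization

Patient-level risk is modelled by main-effects logistic regression on age
(linear, per year), sex, and a set of binary comorbidity flags, fitted by
IRLS (convergence: relative log-likelihood change below 1e-8; perfect
separation is detected by coefficient divergence beyond 15 on the
log-odds scale and reported, never truncated). Candidate comorbidities
are screened on the magnitude of their *adjusted* odds ratio (kept iff
OR >= 2): in administrative datasets with hundreds of thousands of
records, statistical significance alone would admit clinically irrelevant
covariates. Discrimination is summarized by the c statistic, computed
exactly by the rank method with ties counted one half.

Expected counts per hospital are sums of fitted probabilities, and the
adjusted incidence is the indirectly standardized rate
`1000 * (y_j / e_j) * (sum y / sum n)`. A quasi-sentinel indicator
(death in low-mortality DRGs) skips patient-level adjustment entirely and
is analysed on crude rates: the event is so rare and severe that any
occurrence is informative and case-mix modelling is unsupported.

## Systematic variation (question a)

Spread is described by percentile ratios RV95-5 and RV75-25 of the
per-hospital rates (linear-interpolation percentiles; the percentile
convention is not standardized across software, which is why no published
RV value is used as an exact oracle). The inferential statistic is the
Empirical Bayes (EB) estimate: with observed counts `y_j` and expected
counts `e_j`,

    y_j | r_j ~ Poisson(e_j r_j),   log r_j ~ N(mu, sigma2),

and EB is the marginal maximum-likelihood estimate of `sigma2`, the
variance of log relative risks. `sigma2 = 0` means the spread of counts
is fully compatible with Poisson noise. The integral over the log
relative risk is evaluated by *adaptive* Gauss–Hermite quadrature (30
nodes by default), with nodes centered at each unit's posterior mode and
scaled by the posterior curvature. The adaptivity matters: with large
expected counts the Poisson likelihood is far narrower than the prior,
and prior-scaled (non-adaptive) nodes straddle the peak and bias
`sigma2` toward zero — we measured roughly a factor-two downward bias at
`e_j = 500` before centering the nodes. The quadrature agrees with
adaptive `integrate()` to ~1e-11 on test fixtures, and doubling the node
count moves the estimate by less than 1e-4.

Confidence intervals are nonparametric: hospitals (not patients) are
resampled with replacement 2,000 times and the 2.5/97.5 percentiles of
the recomputed statistic are reported. The cluster bootstrap is a design
decision — the question concerns between-hospital variation, and the
hospital is the exchangeable unit. Resamples on which a statistic is
undefined are redrawn and counted; more than 10% undefined aborts the
interval rather than silently conditioning on definedness.

## Cluster effect (question b)

A two-level random-intercept logistic model nests patients in hospitals:

    logit P(event_ij) = x_ij' beta + u_j,    u_j ~ N(0, sigma2).

Three nested fits are reported per indicator: model 1 (random intercept
only), model 2 (adds age and sex), model 3 (adds the screened
comorbidities); the quasi-sentinel indicator gets model 1 only.

Two summaries translate `sigma2` to interpretable scales:

* rho, the latent-variable intraclass correlation
  `sigma2 / (sigma2 + pi^2/3)` — the share of latent outcome variance
  attributable to hospitals, the individual error following the standard
  logistic distribution with variance `pi^2/3`;
* the Median Odds Ratio `MOR = exp(sqrt(2 sigma2) * qnorm(0.75))` — the
  median odds ratio between the higher- and lower-risk hospital for two
  identical patients in two randomly chosen hospitals. `qnorm(0.75)` is
  computed, not the rounded 0.6745, to avoid drift at the second decimal.

Both maps are strictly increasing bijections; intervals for rho and MOR
are the maps applied to a Wald interval for `log(sigma2)`, so the
endpoints transform exactly.

### Estimation

The marginal likelihood is approximated by the Laplace method (default)
or adaptive Gauss–Hermite quadrature (`method = "agq"`). Per-hospital
posterior modes are solved for all hospitals simultaneously by damped
Newton (cost linear in records). The fixed effects are profiled out by a
Newton iteration that uses the *exact* analytic gradient of the Laplace
objective — the envelope theorem handles the profiled mode, and the
log-determinant term contributes a correction through the mode
sensitivity `du*/dbeta` obtained by implicit differentiation — together
with the marginal profile Hessian (conditional information minus the
between-cluster correction). The remaining one-dimensional problem in
`log(sigma)` is solved by golden-section search with a boundary check at
`sigma2 = 0`. This profiled scheme replaced a joint quasi-Newton search
that needed thousands of evaluations on large, ill-conditioned cohorts;
it matches `lme4::glmer` (Laplace) to four decimals on shared fixtures
and converges in a few seconds on 200,000-record cohorts. Standard
errors come from central differences of the analytic gradient at the
optimum.

Accuracy regime: the Laplace approximation error per hospital scales
like the inverse of `m_j p q + 1/sigma2`. On prior-dominated fixtures
(modest `sigma2`, moderate clusters) it is below 1e-3 against exact
integration, which is where the package's Laplace-vs-integration oracle
operates; for small clusters with appreciable `sigma2`, AGQ with 25
nodes tracks exact integration to ~1e-6 and serves as the internal
cross-check (Laplace and AGQ variance estimates agree within 5% on
fixtures with >= 50 records per hospital). National discharge registers
— the intended scale, with thousands of records per hospital — sit well
inside the regime where Laplace is adequate.

## Profiling (question c)

The shrunken residual `u_hat_j` is the mode of the conditional posterior
of `u_j` at the fitted parameters; its comparative standard error is the
curvature at the mode, `1 / sqrt(S2_j + 1/sigma2)`. Shrinkage pulls
low-information hospitals toward 0 in proportion to their information,
which is exactly what disentangles true hospital variation from noise. A
hospital is flagged "above" when `u_hat - 1.96 * se > 0` (alpha = 0.05
two-sided against the population-average prediction), "below"
symmetrically. The flagging scale is the residual (log-odds) scale; the
source material does not state the scale or the interval multiplier, so
both are explicit package decisions, with alpha configurable. No
multiple-testing correction is applied across hospitals, deliberately
matching the screening use of these indicators.

Because of shrinkage, the false-flag rate on null data is *at most*
alpha, not equal to it: when the variance estimate collapses toward
zero, residuals shrink to zero and nothing is flagged. The operating
characteristic tests therefore bound the null flag rate by alpha (plus
Monte-Carlo error) and verify sensitivity on planted outliers
(10 hospitals with `u = +0.8` among 150 nulls; >= 8 must be recovered).

Sensitivity variants re-run the profiling after (i) restricting to the
largest providers (teaching hospitals with strictly more than 450 beds),
the subpopulation most homogeneous in case mix, and (ii) adding a
coding-intensity covariate — the secondary-diagnosis count dichotomized
at the cohort median (a record at the median falls in the high category;
the boundary side is a package decision). Variants are compared by the
Pearson correlation of the residual vectors and the count of flag
changes.

# The synthetic world

The generator emulates a national discharge register at the statistical
level the analyses assume: hospitals with negative-binomial volumes
(heavily skewed, as real registers are), lognormal bed counts with
teaching status increasing in size, Gaussian hospital effects on the
log-odds scale, truncated-normal age, Bernoulli sex and comorbidity
flags, and Bernoulli events from the two-level logistic model. Default
parameters are decubitus-ulcer-like: per-year age OR 1.046, comorbidity
ORs 1.87–5.16, hospital variance 0.38, yielding a pooled rate of a few
per 1,000 — inside the 0.5–17.3 per 1,000 band the studied indicators
span. `calibrate_intercept()` tunes the intercept to any target marginal
rate by solving the Monte-Carlo moment equation, used by tests that
anchor to the 17.3 per 1,000 postoperative-sepsis rate.

Deliberate simplifications, and what they imply for green tests:

* comorbidities are generated independently; real comorbidities
  co-occur. Recovery tests therefore validate estimation under the
  model's own assumptions, not robustness to dependent case mix;
* eligibility is homogeneous (`p_eligible`), with no ICD-code machinery:
  the code-to-flag and numerator/denominator engines are exercised with
  toy mapping tables, and official PSI code lists remain an external
  resource the package does not ship;
* the coding-intensity scenario under-records *recorded* flags
  (hospital-specific detection probability in `[1 - effect, 1]`) and
  scales the recorded secondary-diagnosis count, leaving true risk
  untouched — a recording artifact by construction, matching how the
  phenomenon is framed in the discharge-data literature. The
  secondary-diagnosis law NegBin(mu = 5, size = 2) reproduces the
  reported median of 4;
* all generators are pure functions of `(config, seed)` with documented
  per-stream sub-seeding, so any test is reproducible bit for bit.

# Numerical choices and degenerate inputs

* Percentiles: linear interpolation (`quantile` type 7) everywhere.
* Zero rates: a zero low percentile makes an RV undefined; the default
  policy is an error, with an explicit `"truncate"` alternative that
  substitutes the smallest nonzero rate. (Published tables show a
  quasi-sentinel indicator with a zero 5th percentile *and* a finite
  RV95-5; the package refuses to reproduce that silently.)
* Variance boundaries: both hierarchical fits optimize `log(sigma)` and
  report `sigma2 = 0` with a boundary flag when the optimum collapses;
  cluster-metric intervals then degenerate to the null value with a
  warning rather than a fabricated two-sided interval.
* Convergence reporting for the GLMM is based on the analytic gradient
  at the returned optimum (stationary fixed effects; small profile
  score), recorded in the fit object. A fixed numeric gradient-norm
  cutoff of 1e-6, as one might specify a priori, sits below
  finite-difference noise on 1e5-record objectives and is not used.
* The screening boundary (OR >= 2) is applied with a 1e-9 relative
  guard so that a covariate whose true OR is exactly 2 is kept despite
  optimizer round-off.

# What the acceptance checks establish

Closed-form checks reproduce published rho/MOR values from printed
hospital-level variances and published pooled rates from printed counts.
Simulation checks establish: EB recovery within 10% at J = 200 units
(sigma2 in {0.1, 0.34, 1.1}); GLMM recovery of sigma2 = 0.38 and
model-3-scale odds ratios within 3 SEs on a 150-hospital cohort with
200–500 records per hospital (scaled down from register size, which
only widens the SEs the check uses); oracle equivalence of the
implementation against exact integration, exhaustive pair enumeration
and 2x2 closed forms; the MOR formula against its own pairwise
definition by simulation; flagging operating characteristics; and ~95%
coverage of the bootstrap EB interval at B = 200 over 200 replicates
(scaled down from 2,000 resamples). The headline real-data estimates of
the source study derive from a non-deposited national register and are
not reproducible here; nothing in the package pretends otherwise.

# Known limitations

* No present-on-admission logic, no DRG grouping, no official code
  lists: cohort definitions are config-driven.
* Each discharge is treated as independent; repeat admissions of one
  patient are not linked (the underlying registers are discharge-based).
* The multilevel model is a single random intercept — no random slopes,
  crossed effects or more than two levels.
* The bootstrap treats hospitals as exchangeable; stratified or
  volume-weighted resampling is not implemented.
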