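---
title: "Models and simulation design for CT dose and hematological malignancy risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation design for CT dose and hematological malignancy risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Computed tomography delivers absorbed doses to the active bone marrow
(ABM) in the range of a few to a few tens of mGy per examination.
Whether doses this low raise the incidence of hematological
malignancies in children, adolescents and young adults cannot be
settled by extrapolation from high-dose cohorts; it requires
registry-linked cohorts of CT-exposed patients analysed with models
built for sparse, time-varying, uncertain exposures. `pedctrisk`
implements that analysis chain end to end, together with a synthetic
cohort generator that reproduces the statistical structure such studies
report, so every estimator in the package can be exercised and
calibrated without access to patient data (which studies of this kind
cannot share).

## The risk models

**Excess relative risk (ERR).** The disease rate at attained age $t$
for a person with lagged cumulative ABM dose $Z(t)$ is modeled as

$$\lambda(t) = \lambda_0(t; s)\,\bigl(1 + \beta Z(t-\ell)\bigr),$$

where $s$ indexes strata (sex x country x birth cohort), $\ell$ is the
dose lag (2 years in the main analysis) and $\beta$ is the ERR per mGy,
reported as ERR per 100 mGy. Estimation is by stratified partial
likelihood on the attained-age time scale with left truncation at
entry: at each case's exact diagnosis age the case's relative risk is
compared with the sum over all stratum members under follow-up at that
age. Because the relative risk is *linear* in $\beta$, each risk set
contributes $\log(1+\beta Z_{case}) - \log\sum_j (1+\beta Z_j)$, and the
whole likelihood depends on a risk set only through its size, the
case's exposure and the member exposure sum. No off-the-shelf
proportional-hazards routine fits this model (Cox software is
log-linear in the covariate), which is why the engine is written here;
a log-linear `survival::coxph` fit is used in the test suite as the
small-effect limit against which the linear fit must agree.

The likelihood of the linear model is typically skewed, so the 95%
interval for $\beta$ is profile-likelihood based: the set of $\beta$
within $\chi^2_{1,0.95}/2 = 1.92$ log-likelihood units of the maximum,
found by bisection on each side. $\beta$ is constrained to the
admissible region $\beta > -1/\max Z$ (rates must stay positive);
estimates or bounds that hit the edge carry a boundary flag.
Maximization is by golden-section/parabolic search (`optimize`), which
is deterministic, so identical inputs give bit-identical fits.

**Categorical relative risks and trend.** Cumulative dose is also
analysed in the a-priori categories <5, 5-<10, 10-<15, 15-<25, 25-<50,
>=50 mGy. Category effects are multiplicative ($RR_k = e^{\gamma_k}$,
reference = lowest category) and estimated by the same stratified
partial likelihood with indicator exposures - algebraically a
conditional logistic regression, verified against `survival::clogit` in
the tests. Wald intervals come from the analytic observed information.
The dose-response trend is tested by replacing the indicators with an
ordinal score (category index 0, 1, 2, ... by default; the
category-specific mean dose is available as an option) and comparing
the log-linear slope to the null by likelihood ratio. A person's
category is *time-varying* (their current lagged cumulative dose at
each risk-set age); an end-of-follow-up variant would freeze category
membership and is not what a cumulative-exposure analysis wants.

**Effect modification.** Exposure is decomposed into windows - by age
at exposure (<5, 5-<10, >=10 y) or time since exposure (2-<5, 5-<10,
>=10 y, with the lag as a floor) - and the full model
$RR = 1 + \sum_m \beta_m Z_m$ is compared with the common-slope model
by likelihood ratio with $m-1$ degrees of freedom. The decomposition
conserves the total dose exactly. For sex or birth cohort the
"windows" are subgroup indicators times dose. The multi-coefficient
maximization starts at the common slope, proceeds by Nelder-Mead with a
BFGS polish on the admissible region, and reports per-window profile
intervals.

**Excess absolute risk (EAR).** The grouped-data twin of the
individual analysis: follow-up is split into cells by attained-age band
(5-year default), sex, country, birth cohort and dose stratum, with the
split placed exactly at band boundaries and at dose-step ages (exam age
+ lag), so person-years, case counts and PY-weighted mean doses are
exact. Cell counts are Poisson with rate
$PY \times (\lambda_s + \alpha d)$: a background rate per background
stratum (attained age x sex by default, parameterized on the log scale)
plus an additive excess $\alpha$ per mGy. The canonical unit of
$\alpha$ is cases per person-year per mGy with exact formatters to "per
100,000 (or 10,000) PY per 100 mGy" - published reports use both
conventions, so the canonical unit plus formatters avoids silent
factor-of-ten mistakes. Positivity of fitted rates binds only where
cases were observed; zero-case cells can push their fitted rate to the
boundary, which the optimizer handles with a steep smooth barrier
rather than a discontinuous wall (the profile interval for $\alpha$
would otherwise fail at boundary optima). An identity-link Poisson GLM
serves as the interior-optimum cross-check in the tests; it is not the
implementation because it cannot respect the positivity constraints.

**Projection arithmetic.** The per-examination risk statement is
$100 \cdot \beta \cdot d$ percent at examination dose $d$ (8 mGy for a
typical present-day examination), and the expected excess among $n$
examined persons over $y$ years is $\alpha\, d\, n\, (y-\ell)$: the
lag removes the first $\ell$ of the $y$ post-examination years from
the at-risk period. That reading of the horizon is a design decision;
it reproduces the published "about 1.4 cases per 10,000 examined over
12 years" from the published EAR, and the report echoes the assumption.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions the package emulates:

* nine countries with the published cohort shares; 56% male; birth
  cohorts 1960-2012 with the published bin weights;
* age at first CT drawn from the published bands (30.6% at >=15 y),
  subsequent examinations after exponential gaps (mean 1 y), exam count
  1 + negative binomial with mean 0.52 and dispersion 0.168 - the two
  published moments (mean 1.52, s.d. 1.46) fix both knobs;
* body regions 81% head/neck; per-exam ABM doses lognormal around
  geometric means per (region, age band, period) anchored at the
  published values (head newborn 15 -> 12 mGy across <1991 / 1991-2001
  / >2001, constant 2.6 mGy in near-adults; chest 18 -> 7 mGy);
  unanchored cells are interpolated plausibly between those anchors;
* dose uncertainty in two lognormal components - shared at hospital x
  period level (GSD 1.3) and unshared per examination (GSD 1.8),
  combining to roughly the published "geometric s.d. of the order of
  2"; 200 realizations per examination, with the realization shared
  across examinations of one hospital and period within a realization
  index; multipliers are centered at mean 1 so the ensemble mean is an
  unbiased central dose estimate, and the true dose is one further
  independent draw from the same error model (Berkson-like relative to
  the ensemble mean);
* baseline hazard piecewise constant in attained age and sex at
  pediatric/young-adult hematological-malignancy incidence
  (~7-18 per 100,000 PY, rising with age; overall close to the
  published cohort's 11.5 per 100,000 PY), a true ERR of 0.02 per mGy
  and a 2-year lag;
* registry start years, emigration (Nordic countries only), an
  administrative end two years after the examination-collection window,
  and the person-level flags the sensitivity analyses need (transplant,
  low-reporting hospital, vital status).

Event times are drawn from
$\lambda_0(t,\mathrm{sex})(1+\beta Z_{true}(t-\ell))$ by exact
piecewise-exponential inversion - both factors are step functions, so
no discretization error enters; a fine-grid thinning sampler verifies
the distribution in the tests. The hazard clock starts at the first
examination: events within a year of it exercise the exclusion rules
exactly as the cohort-assembly rules expect.

**What the generator does not emulate:** confounding by indication
(doses are assigned independently of latent disease risk), multiple
primaries, non-hematological first cancers as censoring events,
hospital networks, and any joint dependence of exam count on age at
first CT (independent by construction, as nothing published pins it
down). Passing recovery and calibration tests on these cohorts
therefore demonstrates correctness of the estimators under the stated
model, not robustness to indication bias or to dose-error structure
beyond the two-component lognormal.

## Numerical and design choices

* **Dates** are decimal calendar years; ages are exact differences. The
  at-risk interval is half-open `[entry, exit)` with events at `exit`
  belonging to it; an exam contributes dose when
  `exam age <= t - lag` (boundary inclusive).
* **Ties.** Exactly tied event ages are measure-zero under the
  generator; simultaneous cases would each contribute the full risk-set
  denominator (Breslow-style). Tied exam ages (age-cap clamping) are
  collapsed to single dose steps everywhere a rolling join is used.
* **Percentile truncation** keeps ties at the threshold
  (`dose <= empirical percentile`), making the operation idempotent.
* **Strata** are the printed birth-cohort bins (1960-1979, 1980-1984,
  ..., 2005-2012) crossed with sex and country; empty strata contribute
  nothing; singleton risk sets are counted and contribute no
  information.
* **Unknown morphology codes** go to `unspecified` with a warning -
  silently dropping a malignancy would bias case counts; the
  morphology-to-group mapping ships as an editable CSV covering the
  major ICD-O-3 blocks, with therapy-related codes flagged for
  exclusion.
* **Problem sizes.** The recovery check runs 100 cohorts of 200,000
  persons (~300 cases each, the study's case-count order); test
  calibration uses 500 null replicates of 30,000 persons with the
  baseline raised fivefold (~200 cases); the analysis scripts use
  20,000 persons with a tenfold baseline for the same reason. At a few
  hundred cases the admissible-region boundary
  ($\beta_m > -1/\max Z_m$) sits only about one standard error below
  zero, so negative fluctuations of window coefficients are clipped
  and the heterogeneity LRT runs slightly *conservative* relative to
  $\chi^2_{m-1}$ — the calibration test measures this directly, and
  users should read borderline heterogeneity p-values at modest case
  counts accordingly. Estimator-property
  simulations switch dose uncertainty off (measured dose = true dose):
  they test the estimator, not dose-error attenuation, which with
  classical unshared errors would bias the slope toward zero by design.
* **Leukemia excluding CLL** is carried as a cross-lineage flag on the
  mapping, since it cuts across the lymphoid/myeloid hierarchy.

## Known limitations

The ERR engine materializes risk sets in memory (fine to ~10^6 persons
and ~10^3 cases; a sampled-risk-set mode would be the next step for
larger problems). The EAR background stratification must stay coarser
than the cell classification or the model loses identifiability - the
default (age band x sex) mirrors common grouped-cohort practice. The
generator's dose model interpolates unanchored cells; only the anchored
cells should be read as emulating published dosimetry. Absolute
baseline calibration of the generator is an order-of-magnitude choice,
not a fitted quantity.
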