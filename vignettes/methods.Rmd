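---
title: "Methods: a patient-level outcomes model for type 2 diabetes risk-factor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a patient-level outcomes model for type 2 diabetes risk-factor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dsim)
```

## The model

`t2dsim` is an annual-cycle, patient-level Monte Carlo outcomes model for
type 2 diabetes in the tradition of the UKPDS Outcomes Model and the
East Asian CHIME model family. Each simulated person carries baseline
demographics, diabetes duration, four modelled biomarkers (BMI, HbA1c,
systolic blood pressure, LDL-cholesterol; diastolic pressure is carried
for target classification only) and a prior-complication history. Each
year the person faces:

1. an annual all-cause mortality probability from a logistic equation,
   $p = 1/(1 + e^{-\beta'x})$;
2. for each of 12 complications not yet experienced (haemodialysis,
   myocardial infarction, ischaemic heart disease, heart failure,
   cerebrovascular disease, peripheral vascular disease, neuropathy,
   lower-limb amputation, skin ulcer, chronic kidney disease,
   retinopathy, cataract), a conditional annual probability derived from
   a parametric time-to-event equation,
   $p_t = 1 - S(t)/S(t-1)$, with covariates refreshed each cycle;
3. a deterministic (conditional-mean) one-step update of the four
   biomarkers, optionally overridden by a risk-factor-control scenario.

Death contributes half a year of exposure in its cycle (half-cycle
correction applied to the death year only); no half-cycle correction is
applied elsewhere. Events are drawn after the mortality draw, so a death
cycle accrues no new event costs. Multiple distinct complications may
occur in one cycle; each fires at most once per person, after which its
prior-event flag feeds the other equations (the default catalog routes
these flags into mortality).

### Survival families

Six time-to-event parameterisations are supported, with the covariate
action chosen per family and kept symmetric with the fitter:

| family | form | covariate action |
|---|---|---|
| exponential | $H(t) = e^{\beta'x}\,t$ | proportional hazards |
| Weibull | $H(t) = e^{\beta'x}\,t^{k}$ | proportional hazards |
| Gompertz | $H(t) = e^{\beta'x}(e^{\gamma t}-1)/\gamma$ | proportional hazards |
| log-logistic | $S(t) = [1 + (t e^{-\beta'x})^{1/\sigma}]^{-1}$ | accelerated failure time |
| log-normal | $S(t) = 1 - \Phi[(\log t - \beta'x)/\sigma]$ | accelerated failure time |
| flexible parametric | $\log H(t) = s(\log t) + \beta'x$ | proportional hazards |

The flexible parametric (Royston–Parmar style) model uses a restricted
cubic spline $s(\cdot)$ on log time; the default is the smallest such
model, one internal knot at the median log event time with boundary
knots at the event-time extremes. Monotonicity of the fitted cumulative
hazard is enforced: a spline whose slope is not strictly positive on a
grid spanning the knots is rejected, both at construction and at fit
time. Nesting holds by construction (Weibull with $k=1$ is exponential;
a two-knot spline with zero curvature is Weibull; Gompertz
$\gamma \to 0$ is exponential) and is verified on grids in the tests.

Annual probabilities use conditional survival over $[t, t+1)$ with $t$
measured from model entry; attained age and duration enter as
covariates updated each cycle, so the equations are piecewise-constant
in covariates over cycles. Fitting is maximum likelihood with right
censoring (`optim` BFGS, `reltol = 1e-12`, recorded in each
`fit_result`), and family choice is by AIC ($2k - 2\ln L$) with ties
within $10^{-9}$ resolved in the caller's candidate order. Mortality is
annual logistic regression on person-year data; the annual probability
is taken as-is each cycle (the per-cycle-adjustment alternative is not
modelled, as no convention is stated for it).

## The synthetic cohort: a stated world

The restricted registry cohort behind the published analysis cannot be
shipped, so `cohort_profile()` encodes its published margins as the
default stated world: n = 526 672, 50.3% female, mean age 68.2 y, mean
duration 6.7 y, mean BMI 25.8 kg/m²; target-failure fractions 47.6%
(HbA1c ≥ 7%), 68.3% (BP ≥ 130/80), 18.9% (LDL ≥ 2.6 mmol/L) and 84.9%
for any of the three.

The generator works on a latent one-factor Gaussian structure:

- Each target biomarker's location is **anchored to its threshold**:
  e.g. HbA1c $= 7.0 + \sigma_h (z_h - a_h)$ with
  $a_h = \Phi^{-1}(1 - 0.476)$, which makes the marginal failure
  fraction exact in distribution regardless of $\sigma_h$.
- The three latent variables share a common factor with loading
  $\sqrt{\rho}$; $\rho$ is **calibrated numerically** (1-D quadrature
  over the factor + root finding) so the joint any-failure fraction
  matches 84.9%. Under independence the joint would be 86.5%, so a
  modest positive $\rho \approx 0.1$ is the calibrated solution —
  consistent with the epidemiology of clustered risk factors. Profiles
  whose joint fraction is below the largest marginal or above the
  independence bound are rejected with a diagnostic.
- LDL's location solves a mixture equation, because the failure
  threshold is 2.6 mmol/L in general but 1.8 with prior cardiovascular
  disease (default prevalence 20%, a profile parameter not printed in
  the source material).
- Diastolic BP is systolic minus a positive gap of at least 50 mmHg
  (lognormal excess). The floor guarantees `dbp < sbp` and makes
  `dbp ≥ 80` imply `sbp ≥ 130`, so the joint 130/80 rule reduces
  exactly to the calibrated systolic margin. This is the one place the
  generator deliberately simplifies: isolated diastolic hypertension
  does not occur in the synthetic world.
- Age, duration and BMI are truncated normals whose locations are
  re-solved so the *truncated* means equal the published means;
  duration is capped at age − 18. All biomarkers are clamped to
  physiological bounds chosen so no clamp ever crosses a target
  threshold (HbA1c 4–20%, SBP 70–250, DBP 40–150, LDL 0.3–12, BMI
  12–60).

Standard deviations, correlations, smoking (15%) and prior-CVD (20%)
prevalence and the prior-complication prevalences are **stated
assumptions** surfaced in the profile, chosen once as field-plausible
values; they are not published quantities. Missingness defaults to zero
because the published baseline table is tabulated after imputation;
per-biomarker missingness rates are available for exercising the
sex-specific-mean imputation, which is idempotent and preserves audit
masks.

A green generator test therefore establishes that the *margins* the
published tables state are reproduced and that target flags derive from
the biomarkers themselves. It does not establish realistic joint
tails, within-person longitudinal correlation, or registry-specific
artefacts (coding practices, visit frequency), and no fidelity claim is
made for those.

## Scenarios

Targets are strict inequalities (a value exactly at threshold fails,
matching the ≥ phrasing of the source tables): HbA1c < 7.0%, BP <
130/80 mmHg, LDL < 2.6 mmol/L (< 1.8 with prior CVD). Because "meeting"
a strict target requires a concrete level, each factor has a
configurable attainment value just inside the threshold (defaults:
HbA1c 6.9, SBP 125 / DBP 75, LDL 2.5 / 1.7 with CVD). Control semantics
per cycle:

- a natural-path value that meets the target is left on its natural
  path, and clamped only from the first cycle it would drift past the
  target ("continuously meet targets");
- a failing value is set to the attainment value; with a $k$-year ramp
  it moves linearly from baseline toward attainment, reaching it at
  cycle $k$, and is never set above its natural path;
- partial coverage flags a simple random sample of `round(coverage·n)`
  persons as controlled; the rest follow the natural path.

The four preset scenarios (HbA1c-only, BP-only, LDL-only, combined) and
the natural comparator mirror the published design; the sensitivity
axes are `time_to_target ∈ {1,3,5}` and `coverage ∈ {0.5, 0.75, 1}`.

## Common random numbers

Each person owns a private uniform stream seeded by a deterministic
hash of `(person_id, master_seed)` and indexed by `(outcome, cycle)`.
Scenario changes alter probabilities, never draws, so the same person
receives identical randomness across counterfactuals; the empty
scenario is bit-identical to the natural run and results are invariant
to row order. With mortality disabled, a protective scenario cannot
increase event counts for any equation monotone in the controlled
biomarkers — this exact coupling property is asserted in the tests, and
measured CRN variance reduction on the QALY delta is verified over
replicate runs. Mortality direction is deliberately *not* asserted:
with mortality active, controlled arms can show transiently higher
event counts through survivor dynamics.

Biomarker residuals default to the conditional-mean policy
(deterministic paths, stochastic events), the common low-variance
microsimulation choice; stochastic residuals are available but draw
from a run-level stream rather than person-keyed substreams — a
documented limitation of the sensitivity mode.

## Health economics

Annual utility is additive: baseline utility for uncomplicated type 2
diabetes minus event-year decrements for incident complications,
subsequent-year decrements for prevalent ones, and an excess-weight
decrement per BMI unit above threshold, floored at zero. Costs per
cycle are management plus event-year / subsequent-year complication
costs, scaled by the alive fraction and an inflation factor.
Discounting is annual, end-of-cycle, first year undiscounted:
$(1+r)^{-(c-1)}$ at $r = 3\%$ for both costs and benefits, so a 10-year
unit stream sums to $(1 - 1.03^{-10})/0.03 \times 1.03 = 8.7861$.

Per-person outcomes divide population deltas by the count of persons
failing the scenario's controlled targets at baseline — the rule that
exactly reproduces the published per-person values from the published
population values and baseline counts. The per-complication
decomposition reuses the additive structure, so buckets sum to totals
exactly whenever the utility floor does not bind (with the default
catalogs it does not at tested scales).

The default utility and cost catalogs are **synthetic placeholders**
(flagged as such in their documentation): the published analysis took
them from sources whose unit values are not printed in the main text.
Loaders accept transcribed catalogs for fidelity runs; the sensitivity
bounds scale decrements by ±20%.

## Numerical choices

- Optimiser: BFGS, `maxit = 1000`, `reltol = 1e-12`, numeric Hessian
  for standard errors; non-convergence is flagged, never silent.
- Gompertz uses a series expansion below $|\gamma| < 10^{-8}$ to avoid
  0/0; log-likelihoods return a large penalty on non-finite values.
- Inverse-CDF event sampling has closed forms for five families and a
  bisection solve on the spline scale for the flexible parametric
  family; a Gompertz with $\gamma < 0$ can return an infinite time
  (cure fraction), which administrative censoring handles.
- `S(t) = 0` in the annual-probability denominator yields probability 1
  with a warning; negative times are errors.
- AIC ties (within $10^{-9}$): first candidate in caller order wins.

## Known limitations

- No competing-risks likelihood: outcomes are separate equations, as in
  the modelled analysis; no recurrence of a complication.
- No left truncation / delayed entry in the fitters.
- No treatment pharmacology, adherence dynamics, adverse events or
  indirect costs; scenarios override biomarker paths rather than model
  therapies.
- The default coefficient catalogs are synthetic; every quantitative
  claim in this package's tests is about arithmetic, calibration,
  closed forms and recovery of *known* synthetic truths — not about the
  published population estimates, which require the restricted cohort
  and unpublished fitted coefficients.
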