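---
title: "Population pharmacokinetics and virtual TDM of isavuconazole"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics and virtual TDM of isavuconazole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`isatdm` implements a complete analysis chain for therapeutic drug
monitoring (TDM) data of the triazole antifungal isavuconazole:

1. a structural population pharmacokinetic (popPK) model with covariate
   effects (`pk_core`),
2. nonlinear mixed-effects estimation with the model-selection toolkit
   used in popPK practice (`fit_poppk`, `lrt_compare`, `aic_compare`,
   `stepwise_covariates`, `cwres`, `bootstrap_poppk`),
3. external-validation metrics and prediction-corrected visual
   predictive checks (`mpe`, `rmse`, `pcvpc`),
4. MAP-Bayes individual exposure estimation (`map_fit`,
   `exposure_at_date`),
5. exploratory exposure–response and exposure–toxicity logistic
   regressions (`fit_exposure_outcome`, `sensitivity_refit`),
6. a synthetic-cohort generator that emulates routine hospital TDM data
   (`generate_cohort`), and
7. a 10,000-patient steady-state simulator comparing TDM dose-adjustment
   strategies (`simulate_cohort`, `apply_strategy`).

Hospital TDM records are confidential and not redistributable, so every
stage of the package is exercised on synthetic data whose statistical
structure mirrors the real cohorts: the generator is first-class, tested
code, not a fixture.

# The model

Isavuconazole concentrations follow a one-compartment model with
first-order absorption and linear elimination. Individual parameters are
log-normal around the typical values, with body mass index (BMI) scaling
the volume of distribution:

$$CL_i = TVCL \cdot e^{\eta_{CL,i}}, \qquad
  V_i = TVV \cdot \left(\frac{BMI_i}{25}\right) \cdot e^{\eta_{V,i}},
  \qquad k_{a,i} = k_a,$$

with $\eta \sim N(0, \omega^2)$ independently for $CL$ and $V$.
Observed concentrations carry a mixed residual error,
$y = f\,(1 + \varepsilon_p) + \varepsilon_a$ with
$\varepsilon_p \sim N(0, \sigma_{prop}^2)$ and
$\varepsilon_a \sim N(0, \sigma_{add}^2)$.

`isa_final_model()` carries the published estimates: $TVCL$ 2.3 L/h,
$TVV$ 523 L, $k_a$ fixed at 2.5 h$^{-1}$ (giving a time-to-peak of about
2.6 h), $\omega_{CL}$ 0.37, $\omega_V$ 0.34, proportional error 19%, and
additive error 0.73 mg/L. `isa_base_model()` is the pre-covariate
structural model (CL 2.2 L/h, V 550 L). Oral bioavailability is 100%
(no oral/IV difference), so oral and intravenous doses superpose with
the same clearance.

A note on conventions: an interindividual variability printed as
"CV% = 37" is interpreted as a log-scale standard deviation
$\omega = 0.37$. The alternative convention
$\omega = \sqrt{\log(1 + CV^2)}$ differs by under 2% at these
magnitudes; `cv_to_omega(cv, exact = TRUE)` converts under the exact
convention when needed.

Key derived quantities are closed-form: steady-state trough
(`cmin_ss`), steady-state AUC over a dosing interval
($F \cdot D / CL$, `auc_ss`), $T_{max} = \ln(k_a/k_e)/(k_a - k_e)$
(`tmax`) and half-life $\ln 2 \cdot V / CL$ (`half_life`). The tests pin
each closed form to an independent numeric oracle (long-run dose
superposition, trapezoidal integration, grid argmax).

# Estimation

`fit_poppk` maximizes the marginal likelihood with the integral over the
two random effects approximated by Laplace's method at the per-subject
posterior mode — the classical deterministic approach for sparse PK
data. The inner mode search is a damped (Levenberg–Marquardt) Newton
iteration on analytic gradients, compiled in C++; trough-only designs
can produce long curved valleys and occasional multimodality in the
joint objective, so the damping schedule and a fixed fan of fallback
starts keep the search deterministic and monotone. The outer
optimization runs Nelder–Mead on log-parameters with simplex restarts
and (by default) three deterministically jittered starting points, since
no reference starting values exist for an arbitrary dataset.

Numerical accuracy of the marginal likelihood is guarded two ways.
First, the Laplace value is compared in the tests against nested
adaptive quadrature on small cohorts; the approximation error under the
final model's residual-error magnitudes is typically 0.03–0.25% of the
objective function value (OFV). This is a property of the Laplace
approximation itself, not of the implementation: the package also
provides `marginal_neg2ll(..., method = "agq")`, an adaptive
Gauss–Hermite refinement centred at the same mode, which agrees with the
quadrature oracle to better than 0.001% at 11 nodes per dimension and
converges to the exact integral. Estimation defaults to Laplace for
speed and for comparability with standard popPK workflows; AGQ is the
accuracy-critical evaluation path.

Relative standard errors come from the observed-information Hessian of
the OFV on the log-parameter scale (a log-scale SE approximates a CV on
the natural scale). Empirical Bayes estimates (EBEs) are the final
posterior modes; shrinkage is $100(1 - SD(EBE)/\omega)$.

## Model selection

- `lrt_compare`: forward inclusion accepts a nested extension when
  $\Delta OFV \le -3.84$ (df 1, $p = 0.05$; the boundary is inclusive),
  backward deletion keeps a term only when removing it costs more than
  6.63 ($p = 0.01$). Thresholds generalize through the $\chi^2$ quantile
  for df > 1.
- `aic_compare`: non-nested alternatives need an AIC lower by at least 2.
- `stepwise_covariates`: forward steps add the single best relation per
  cycle (best $\Delta OFV$ first), then backward deletion prunes at the
  stricter level; the returned trace records every tested relation, and
  retained relations are annotated with the IIV-variance reduction they
  explain. Candidate forms are power on a normalized covariate, linear
  centred on the reference, or a categorical shift; continuous
  references default to the cohort median.
- `cwres`/`cwres_flag`: first-order conditional linearization around the
  EBEs; observations with |CWRES| > 3 are flagged as outliers. On
  self-simulated data at the true parameters the CWRES are standard
  normal to well within the tested tolerances.
- `bootstrap_poppk`: nonparametric subject-level resampling
  (unstratified — the analysis treats the estimation cohort as one
  population), defaulting to 2000 replicates in production use; tests
  use far fewer.

A sensitivity hook mirrors routine practice of re-estimating after
removing observations drawn earlier than 6 h post-dose: filter the
subjects' observation tables and refit.

# Individual (MAP-Bayes) exposure

`map_fit` minimizes the joint $-2\log$-likelihood
$\sum_j [\log v_j + (y_j - f_j)^2 / v_j] + \eta^T \Omega^{-1} \eta$ over
the two random effects. With no usable observations the prior mode
(typical values) is returned; as $\omega \to 0$ the estimate collapses
to the typical values and as $\omega \to \infty$ it approaches the
per-subject least-squares fit (both limits are tested).

`exposure_at_date` derives the two clinical exposure metrics at an
evaluation date: the model-predicted trough immediately before the next
dose after the date (one nominal interval after the last dose when
therapy has stopped), and the daily AUC as daily dose in force divided
by the MAP clearance. Eligibility requires a concentration measurement
within 50 days of the date (inclusive, in days); the daily dose in
force is the sum of doses in the preceding 24 h, falling back to the
most recent dose assumed once daily. All observations of a subject
inform the MAP fit; the 50-day window gates eligibility only.

# The synthetic cohort generator

`generate_cohort` emulates the structure of routine-TDM datasets from
hospitalized adults treated for invasive fungal infection:

- 41 subjects by default, each with Poisson(4) samples truncated to
  1–11 (median 4);
- once-daily maintenance doses from {100, 200, 300, 400} mg weighted
  toward the standard 200 mg;
- half the subjects start intravenously (1-h infusions) for the first
  40% of treatment before switching to oral, putting ~80% of samples
  under oral dosing;
- sampling times are 80% troughs (30 min before a dose) and otherwise
  1–8 h post-dose, over treatments of 10–28 days;
- BMI is truncated-normal (mean 24, SD 5.5) inside 12–40 kg/m²; age,
  weight, height, sex, creatinine, bilirubin, albumin and ALT match the
  published cohort's medians and ranges; eGFR comes from the 2009
  CKD-EPI equation (race-free form);
- concentrations are simulated from the generating model with mixed
  residual error, redrawn when a draw is non-positive (a measured
  concentration cannot be negative);
- covariates other than BMI carry no true effect, deliberately
  exercising the covariate engine's type-I behaviour;
- a hidden truth table retains each subject's random effects and true
  exposures for recovery tests.

Treatment success is Bernoulli with
$P = \text{logit}^{-1}(-2.1 + 1.5 \ln C_{min,true})$, calibrated so the
average success rate is ~43% at the cohort's exposure distribution;
hepatotoxicity is a constant 28% (a null exposure–toxicity model).

Two features of real data are *not* emulated: assumed (imputed) dosing
times with unknown error, beyond an `imputed` flag in the data dialect,
and time-varying covariates within a treatment (labs are generated at
baseline). Passing tests therefore demonstrate the correctness of the
machinery under the stated generative model, not robustness to
real-world time-recording errors.

The redraw-if-non-positive rule makes low observed concentrations a
(slightly) truncated Gaussian while the likelihood assumes an
untruncated one. This is visible as a small downward bias in the
additive error and volume estimates in the recovery tests (the worst
fixed-effect bias is about −7% on $TVV$ under trough-heavy designs) —
an intrinsic cost of requiring positive simulated measurements under a
large additive error component, documented here rather than hidden by
changing the error model.

# The virtual TDM study

`simulate_cohort` draws 10,000 patients at steady state on 200 mg once
daily: BMI uniform on (12, 40) kg/m², random effects from the final
model, and a plausibility filter that redraws (CL, V) pairs whose
half-life falls outside 40–400 h. The published analysis filtered on
the half-life range observed in its patients without printing the
bounds; 40–400 h brackets the plausible clinical range around the
typical 158 h, the bounds are configurable, and an acceptance test
verifies the attainment figures move by less than 2 points when the
filter is widened to 30–500 h.

Each patient records the true steady-state trough, the true AUC
(dose/CL), and one observed trough with residual error (non-positive
draws redrawn). Dose adjustment targets the geometric mean of the
therapeutic range (3.54 mg/L for troughs 2.5–5.0; 118.2 mg·h/L for AUC
60–233) using the proportional rule
`new = current * target / estimate`, rounded to the nearest dose in
{100, 200, 300, 400} mg with midpoint ties broken toward the lower
(safer) dose. Strategies differ in the estimate fed to the rule:

- `proportional_cmin`: the noisy observed trough itself;
- `mipd_cmin` / `mipd_auc`: the MAP-Bayes trough or AUC computed from
  that single observed trough (a vectorized damped-Newton MAP over the
  whole cohort).

A design choice worth stating explicitly: **doses are adjusted only when
the monitored estimate falls outside its target range.** This is how TDM
is practised — a patient whose measured trough is on target is left
alone — and it is the reading under which the package reproduces the
published attainment percentages; re-dosing every patient toward the
geometric mean would *lower* post-TDM attainment for patients already on
target because measurement noise would push many of them off their
correct dose. The behaviour is switchable
(`tdm_strategy(..., adjust_outside_only = FALSE)`).

One measurement triggers one adjustment cycle; multi-cycle adaptive TDM
is out of scope. After re-dosing, true exposures rescale linearly with
dose (the model is dose-proportional) and attainment is summarized with
inclusive bounds.

With the default settings the package computes (n = 10,000, seed 1):
63–65% of patients inside the trough range and ~84% inside the AUC
range before TDM; ~73% (proportional) and ~76% (MIPD) trough attainment
and ~89% AUC attainment after trough-targeted adjustment; ~69% trough
and ~89% AUC attainment after AUC-targeted adjustment. These are the
quantities the acceptance tests assert and `scripts/acceptance.R`
recomputes.

# Exposure–response analysis

`fit_exposure_outcome` fits a maximum-likelihood logistic regression of
a binary outcome on log-exposure ($\ln C_{min}$ or $\ln AUC$) with the
p-value from the likelihood-ratio test against the intercept-only model
— preferred over the Wald test at TDM-cohort sample sizes. Complete
separation is detected and reported (`separated = TRUE`, no p-value)
rather than fabricating one. `sensitivity_refit` re-runs the analysis
under labelled record-removal rules: dropping a centre, dropping
exposures outside stated quantiles, or dropping explicit subject ids
(the published outlier was identified clinically, not numerically, so an
id list is the faithful representation).

# Numerical choices and degenerate inputs

- Residual variance is floored at $10^{-12}$ so that zero-noise
  configurations (used to test the proportional-vs-MIPD equivalence)
  remain computable.
- $\omega = 0$ is replaced by $10^{-8}$ inside the likelihood: the OFV
  then equals the fixed-$\eta$ Gaussian deviance, which is tested.
- `ka = ke` is rejected as degenerate (unreachable with the published
  parameters).
- Dose-rounding midpoint ties go to the lower dose; the boundary of the
  lab dichotomization rule (exactly twice the upper limit of normal)
  maps to 0 (strict inequality); covariate values outside the
  quantified window carry the nearest value.
- Every stochastic routine takes an explicit seed; the pipeline derives
  one stream per stage from the global seed and the stage name, so
  stages are independently reproducible.

# Problem sizes used by the test suite

The suite chooses sizes that make the statistical assertions
well-powered while staying desk-scale: 10,000 virtual patients for the
attainment checks (Monte-Carlo SE ≈ 0.5 points); 20 replicates of
200-subject cohorts for parameter recovery; 10 replicates of
100-subject cohorts (8 samples each, mostly post-dose) for the stepwise
covariate engine, where trough-only designs would leave the volume — and
hence its BMI effect — weakly identified; 150 subjects for the CWRES
calibration; and 60 subjects with 300 simulation replicates for pcVPC
coverage.

# Known limitations

- The Laplace OFV carries 0.03–0.25% approximation error under the
  final model's residual-error magnitudes; use `method = "agq"` where
  that matters.
- The positivity redraw in the generators induces the small recovery
  biases quantified above.
- Single-adjustment TDM only; no loading-dose phase; no
  protein-binding or QT-exposure submodels.
- The exposure–response module consumes binary outcome labels; it does
  not implement infection-classification or outcome-adjudication logic.
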