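---
title: "Model and methods: discrete-time microsimulation of prediabetes and diabetes outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`diabsim` implements an individual-level, annual-cycle simulation of disease
progression for adults with prediabetes or type 2 diabetes. Thirteen
outcomes are modelled — all-cause mortality; the macrovascular events
myocardial infarction, ischemic heart disease, heart failure and
cerebrovascular disease; the microvascular events peripheral vascular
disease, neuropathy, amputation, skin ulcer, renal failure, cataract and
retinopathy; and, for prediabetic individuals, development of diabetes.

## Risk equations

Each outcome has a parametric accelerated-failure-time (AFT) survival
equation on the time-since-enrollment scale,

$$\log T = \beta_0 + \textstyle\sum_j \beta_j x_j + \sigma W,$$

with $W$ following the extreme-value (Weibull; exponential when
$\sigma = 1$), logistic (log-logistic) or normal (log-normal) law. A
coefficient's exponential $e^{\beta_j}$ is a *survival time ratio*: values
above 1 lengthen the time to the event (protective). The AFT
parameterization is used throughout because effect sizes are reported and
interpreted as survival time ratios; for the Weibull and exponential
families this is an exact reparameterization of the proportional-hazards
form, and for the log-logistic and log-normal families AFT is the only
coherent reading.

Continuous predictors may enter nonlinearly through a 3-knot restricted
cubic spline, with knots placed at the 10th, 50th and 90th percentiles of
the development data (type-7, linear-interpolation percentiles — the knot
values shift with the percentile rule, so the rule is fixed and stated).
The spline contributes one linear and one nonlinear basis column per
variable, with the nonlinear component in the `(k3 - k1)^2`-normalized
form used by the `rms` toolchain.

## The annual cycle

The engine advances the whole cohort one year at a time. Within a cycle, an
equation's contribution is converted to an annual event probability by the
standard discrete-time embedding of a continuous-time survival model,

$$p_u = 1 - S(u + 1 \mid \eta) / S(u \mid \eta),$$

with covariates frozen at their cycle-start values. Events are drawn as
independent uniforms per outcome in a fixed order (mortality first, the
other outcomes alphabetically). Every applicable outcome is drawn even in a
cycle where death fires, so times to other outcomes in the death cycle are
still recorded. Outcomes with a history flag are absorbing: after the first
occurrence the flag becomes a covariate and the outcome is not re-drawn,
because the equations model first events. Events are dated at the end of
the cycle (integer times, no half-cycle correction). Survivors then have
age, time since enrollment, diabetes duration, histories and biomarkers
updated for entry into the next cycle; development of diabetes switches the
glycemic status with duration restarting at zero.

Seven biomarkers (HbA1c, systolic and diastolic blood pressure, HDL and LDL
cholesterol, triglycerides, BMI) progress by linear equations in the two
lagged annual averages, age, sex, duration and medication use, each with a
residual root-mean-square error available for stochastic draws. At the
first cycle both lags are initialized to the baseline value (an unbiased
cold start; the data-generating choice when no pre-enrollment history
exists). eGFR, hemoglobin and white-cell count are risk-equation covariates
but are *not* progressed — they are held at baseline, a recorded
limitation. Medications are held fixed at baseline unless a treatment
schedule overrides a biomarker.

## Estimation

Equations are fitted from a person-period panel by censored maximum
likelihood, with time-varying covariates entered as (start, stop] episodes:
an event-free episode contributes $\log S(t_{stop}) - \log S(t_{start})$,
an event episode contributes either the exact-time log density (`timing =
"exact"`, for continuously observed event times) or the conditional
within-cycle mass $\log[1 - S(t_{stop})/S(t_{start})]$ (`timing =
"interval"`, the default — correct for annual panels where events are known
only to the cycle; using the density form on cycle data biases the fit).
Optimization is BFGS on $(\beta, \log\sigma)$ with relative tolerance
1e-10 and at most 200 iterations; non-convergence is flagged, never
silent. Standard errors come from the inverse observed information.

Panel preparation averages repeated within-year measurements (this *is* the
annual moving-average smoothing of biomarkers), carries values forward
over gap years with a flag, propagates history flags monotonically (an
event at baseline or in any earlier cycle is history for the current
cycle), and constructs per-outcome risk sets (alive, no prior history of
that event, prediabetic for development of diabetes).

The AFT family is selected by AIC over the four candidates, ties broken by
simplicity (exponential first). AIC backwards selection is available but
optional, since in practice variable selection is combined with clinical
judgment, which is outside this package's scope. Parameter (second-order)
uncertainty comes from bootstrap resampling of individuals — every
person-period of a resampled individual travels with them — and refitting;
first-order uncertainty from Monte Carlo replicates of the simulation.
Overfitting bias in discrimination is corrected by Harrell's bootstrap
optimism procedure (corrected = apparent − mean over replicates of the
bootstrap-vs-original performance gap), with the Brier score at a fixed
horizon treated the same way.

## Simulated trial cohorts

To reproduce aggregate published arms, continuous baselines are drawn from
truncated normal distributions (reported mean/SD, protocol bounds;
rejection sampling), binary traits as Bernoulli draws at the reported
prevalence, each variable sampled independently (marginal sampling —
correlations between baseline covariates are deliberately ignored). The
full treatment effect on a biomarker is an absolute change expressed as a
fraction of the arm's baseline mean and is reached in year 2 as a step: the
year-1 value is reduced by the relative effect and held stable thereafter.
Endpoint percentages come from at least 100,000 simulated participants,
with a running-mean convergence diagnostic per reported endpoint.

## Validation battery

* **Harrell's C**: concordant over usable pairs; a pair is usable iff the
  strictly shorter follow-up time ended in an event; score ties count 0.5;
  percentile-bootstrap CI over individuals (default 100 replicates).
* **Calibration**: individuals grouped into quantiles of predicted risk,
  starting at deciles; while any group has fewer than 5 observed events and
  more than 3 groups remain, the group count is reduced by one (3 is the
  floor). Slope and intercept come from an unweighted OLS line of observed
  proportion on mean predicted risk across groups.
* **RMSPE**: root mean square error between predicted and observed endpoint
  percentages, in percentage points. An alternative reading (relative
  error, each difference divided by the observed value) exists in the
  literature; because reported values of a few percent alongside
  percentage-scale endpoints imply the absolute form, absolute is the
  default and `mode = "relative"` is a flag.
* **R²** is computed about the identity line of the predicted-versus-
  observed scatter, not a refitted line — the quantity a predicted/observed
  scatterplot annotates.
* Observed status at a 10-year horizon uses event-by-horizon among
  individuals with an event by then or follow-up reaching it; individuals
  censored earlier are excluded (inverse-probability weighting would be the
  refinement, not the default).

# The synthetic cohort: what it emulates, and what a green test establishes

No individual-level development data can ship with the package, so
`generate_cohort()` manufactures a longitudinal cohort with *known ground
truth*: baseline distributions anchored to the published baseline table of
a Hong Kong clinical-records cohort (e.g., prediabetes HbA1c mean 5.9
SD 0.3, diabetes 7.8 SD 1.7, 43.5% diabetes mix), trajectories from known
mean-reverting AR(2) biomarker equations, per-cycle Bernoulli events from a
known AFT bundle, and administrative censoring from staggered entry over a
12-year accrual window with a fixed end date (each individual's cap uniform
over 1..12 cycles).

The default equation bundle's intercepts are anchored so that the 10-year
survival at the cohort's mean covariate profile equals that of a stated
constant annual rate — 0.025 per person-year for mortality, matching the
published crude death rate, and plausible rates for the other outcomes
(e.g., 0.008 for ischemic heart disease and cerebrovascular disease, 0.06
for diabetes onset among prediabetes). Anchoring at the 10-year horizon
rather than the first cycle keeps rising-hazard families (log-normal,
log-logistic) from overshooting at later cycles; covariate heterogeneity
still inflates cohort-level rates somewhat above the anchor (Jensen's
inequality on a convex tail), which is accepted and documented rather than
tuned away.

What the generator does **not** emulate: real missingness patterns (a
missing-at-random masker would be an extension), correlated baseline
covariates, medication changes over time, measurement error distinct from
biological drift, and recurrent events. A green end-to-end test therefore
establishes that estimation recovers known generating parameters from data
of the stated structure and that the simulator reproduces its own
closed-form laws — not that the shipped default equations are clinically
validated coefficients. Real use requires fitting to real panel data via
`fit_bundle()`.

# Numerical and design choices

* **Self-consistency checks freeze covariates.** With updating disabled the
  drawn process follows the parametric $S(t)$ exactly, so a 10-year
  baseline-covariate prediction is the correct expectation of its own
  simulation; that is the configuration in which calibration
  slope/intercept are asserted to be 1/0. With updating enabled, a
  baseline-frozen prediction is *not* the expectation of the dynamic
  process (age drift alone inflates late-cycle risk), so the corresponding
  check validates per-cycle predicted probabilities against per-cycle
  events instead. Fitted (rather than true) equations add estimation noise
  of roughly ±0.1–0.2 to a decile calibration slope at n = 20,000; the
  slope bands are asserted for the generating equations.
* **Event-history trials population.** A trial arm whose entire population
  carries a history flag (e.g., established coronary disease) gets a
  structural zero for that outcome's incidence, because first-event
  equations never re-draw it. Trials report recurrent events there; this is
  a known limitation of the absorbing-outcome convention.
* **RNG.** All draws flow through R's default generator from one seed;
  within a cycle, draws are vectorized over the full cohort per outcome in
  a fixed order. This yields bit-reproducibility, independence from
  iteration order, and common random numbers across equal-sized arms —
  the properties a counter-based per-(individual, cycle, outcome) stream
  would provide — without platform-dependent machinery.
* **Degenerate inputs.** Constant covariates in a trajectory fit are
  dropped with a warning (coefficient 0) unless the lag structure itself is
  collinear, which errors; fewer than 3 distinct spline percentiles demote
  a variable to linear with a warning; `S(u)` underflowing to zero floors
  the annual probability at 1 with a warning; bounds excluding more than
  99.9% of a truncated normal's mass are rejected as a specification error.
* **Serialization.** Model JSON is written with 17 significant digits so
  a write/read round-trip reproduces every coefficient bit-exactly.
* **Configs are JSON** (fit specifications, trial arms): a single
  serialization format for models, manifests and configs keeps the I/O
  surface dependency-light.

# Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `horizon` | — | years | simulation length; lifetime projections use large values |
| `knot percentiles` | 10/50/90 | — | spline flexibility vs stability |
| `timing` | `"interval"` | — | annual panels observe events to the cycle |
| `reltol` / `maxit` | 1e-10 / 200 | — | cross-platform reproducible fits |
| `B` (bootstrap) | 100 | replicates | CI and optimism stability |
| calibration floor | 3 groups, 5 events | — | prevents unstable group estimates |
| `n_simulated` | 100,000 | participants | trial endpoint convergence (< 0.2 pp drift over the final 50,000) |
| treatment start | year 2 | — | full effect reached in year 2, stable thereafter |

# Known limitations

Hypoglycemic episodes and other unrecorded complications are out of scope;
eGFR, hemoglobin and white-cell count do not progress; outcomes are
absorbing first events; baseline covariates in trial arms are sampled
independently; costs and quality-of-life weights are not modelled.
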