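---
title: "Session dosing: modelling depressive symptom dynamics from mental healthcare utilisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Session dosing: modelling depressive symptom dynamics from mental healthcare utilisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sessiondose)
```

## The model

`sessiondose` treats mental healthcare sessions — coaching, therapy and
psychiatry appointments — as unit therapeutic inputs ("doses") whose effect
on depressive symptom severity is indirect: each session deposits one unit
of latent mass into its service compartment, the mass decays with a
first-order rate constant $k_{out,s}$ specific to the service type, and the
combined mass across compartments,

$$\mathrm{TRT}(t) = \sum_{\text{sessions } j \,:\, t_j \le t}
  e^{-k_{out,s(j)}\,(t - t_j)},$$

inhibits the *production* of symptoms through a capacity-limited
(Hill-type) term with the maximum effect fixed at 1:

$$\frac{d\,\mathrm{Dep}}{dt} =
  r\left(1 - \frac{\mathrm{TRT}(t)}{\mathrm{TRT}(t) + S_{50}}\right)
  - r\,\mathrm{Dep}, \qquad \mathrm{Dep}(0) = 1 .$$

Severity is the average of the two depression items of a routine
self-report questionnaire (anhedonia and depressed mood, each scored 0–4),
normalised by 4 to $[0,1]$. Using the same rate $r$ for production and
elimination caps severity at the severe entry level 1: an untreated severe
patient stays severe, treatment can push severity down towards
$S_{50}/(\mathrm{TRT}+S_{50})$, and after care stops severity relaxes back
to 1 at rate $r$. Because the maximum inhibition is 1, treatment can at
most switch symptom production off — the bounded parameterisation. The
analogous model that *stimulates* symptom elimination requires an unbounded
stimulation parameter and is deliberately not implemented.

Parameters are latent-scale quantities without direct clinical units; their
value lies in comparative interpretation (faster/slower dissipation of a
session's effect, more/less input needed to sustain a response).

### Assumptions worth stating plainly

* Sessions act only through their timing and type; content, provider and
  life events are invisible to the model.
* Unit bolus per session is an arbitrary but harmless normalisation — it
  fixes the scale of the latent mass, and $S_{50}$ absorbs the rest.
* Co-timed sessions stack additively (two boluses).
* Every modelled patient enters severe, so $\mathrm{Dep}(0)$ is fixed at 1
  and is not estimated; `dep0` is exposed as a parameter (default 1,
  values outside $(0,1]$ rejected) to support future non-severe cohorts.
* Time is measured in real-valued days from each patient's baseline.

## Numerical treatment of the trajectory

$\mathrm{TRT}(t)$ is computed analytically (superposed exponentials), never
by numerically integrating the service compartments, which reduces the
system to a single ODE for severity. That ODE is solved with an adaptive
explicit Runge–Kutta method (Cash–Karp 4(5)) at absolute/relative
tolerances $10^{-8}$, with mandatory restarts at every session time because
the right-hand side has a derivative discontinuity at each bolus. Between
restarts the three per-service masses are carried in closed form, so the
cost of one right-hand-side evaluation is independent of the number of
historical sessions.

Within the test-suite the solver is checked against an independent
integrating-factor solution
$\mathrm{Dep}(t) = e^{-rt}\,dep_0 + r\int_0^t e^{-r(t-s)}(1 - I(s))\,ds$
evaluated by adaptive quadrature split at event times; agreement is
required to $10^{-6}$ across random parameter/schedule draws. Solver
failures (step-size underflow, non-finite states) raise errors — severity
is never silently clamped.

Inside the stochastic E-step of the population fit only, tolerances are
relaxed (relative $10^{-4}$, absolute $10^{-6}$, configurable): the
resulting trajectory error is orders of magnitude below the residual
noise the trajectories are compared against, and the sampling loop
performs millions of solves. Empirical-Bayes estimation and all reported
predictions use the tight $10^{-8}$ default.

## The hierarchical layer and its estimation

Individual parameters are log-normal around the typical values:
$\theta_{i,p} = \mu_p e^{\eta_{i,p}}$, $\eta_{i,p} \sim N(0,\omega_p^2)$
with a diagonal $\omega$ (no correlation structure is assumed), and
observations carry additive Gaussian residual error with a single
standard deviation $\sigma$ shared by all patients and times; both
$\omega$ and $\sigma$ are estimated. Log-normal random effects match the
positivity of all five parameters and the right-skewed shape typical of
rate-constant distributions. Baseline (time-0) observations are excluded
from the likelihood: the model initialises severity at the observed entry
level, so those residuals are structurally zero and would only bias
$\sigma$ downward.

Estimation uses stochastic approximation EM (SAEM):

* **E-step** — for each patient, a few Metropolis–Hastings transitions on
  several parallel chains of individual log-parameters, targeting the
  conditional posterior under the current population parameters. Proposals
  are multivariate random walks whose covariance is the pooled sample
  covariance of all chains (Haario-style adaptive Metropolis with a small
  diagonal floor and the classical $2.38/\sqrt{d}$ scaling); a per-patient
  scalar additionally adapts toward a target acceptance rate of 0.3.
  Both adaptations are frozen when the smoothing phase starts.
* **M-step** — stochastic-approximation averages of the complete-data
  sufficient statistics update $\log\mu$, $\omega$ and $\sigma$, with step
  size 1 during the exploration phase and $1/k$ during the smoothing
  phase. During exploration, $\omega$ and $\sigma$ may shrink by at most
  5% per iteration (simulated annealing), which keeps the chains mobile
  while the variances contract.

Defaults are 300 exploration + 100 smoothing iterations, 3 chains and 5
transitions per patient per iteration — all configurable via
`saem_config()`. The default initial typical values ($k_{out}$ = 0.05,
0.1, 0.2/day for coaching, therapy, psychiatry; $S_{50}=1$; $r=0.05$/day)
are engineering choices reflecting the clinical triaging hierarchy of the
three services, not estimates from any dataset. A patient with no sessions
of some type contributes no information on that service's $k_{out}$; their
deviation simply shrinks to the population prior, with no special-casing.

Determinism: one root seed fans out to per-patient, per-iteration RNG
sub-streams keyed by patient id, and patients are processed in id order,
so permuting the input cohort cannot change any estimate.

After the population fit, each patient's empirical-Bayes (MAP) deviations
are found by multi-start local optimisation of the penalised objective
(`individual_objective()`); the prior term pins parameters with
$\omega_p = 0$ at the typical value.

Monte-Carlo character of SAEM: with weakly identified parameters (few
sessions of a service per patient), the estimate retains stochastic
scatter that shrinks with the length of the smoothing phase. The recovery
studies below therefore use a longer smoothing phase (200–300 iterations)
than the interactive default.

## Triage of individual fits

The model is not expected to support every patient's data equally: a
sparse record, or symptoms driven by factors outside the schedule, yield
poor individual fits. Fit quality is judged on individual weighted
residuals, $\mathrm{IWRES} = (\text{observed} - \text{individual
prediction})/\sigma$, with all time-0 observations removed (their
residuals are structurally zero). The absolute mean and the sample SD
(with $n-1$ denominator, a choice this package makes explicit) of a
patient's IWRES are graded separately —

| grade | abs. mean IWRES | SD of IWRES |
|---|---|---|
| supported | $\le 1$ | $\le 1.5$ |
| semi-supported | $(1, 1.5]$ | $(1.5, 2]$ |
| unsupported | $> 1.5$ | $> 2$ |

— and the patient receives the *worse* of the two grades. The grading
thresholds are applied inclusively exactly as printed (a value equal to a
threshold takes the better class). How to combine a conflicting mean grade
and SD grade is genuinely open; this package takes the worse grade as the
cautious clinical choice — a questionable fit should be flagged for
review, not promoted — and isolates the rule behind the single operation
`classify_support()`. Patients with fewer than two post-baseline
observations cannot be classified at all and are reported as a separate
class; they still inform the population fit. Cohort tabulations report
percentages on both bases (all patients, and classifiable patients only).

## Treatment planning

Schedules are declarative — "therapy every 14 days over days 0–180"
(`therapy:q14d:0-180` in the mini-language) — and expand to concrete
session events, start-inclusive and end-exclusive. Plans are simulated
from the severe entry level over a horizon (the package's worked examples
use 180 days of treatment followed by 180 days without, a planning pattern
for re-engagement) and summarised against a response threshold:

* the default threshold is 0.625, the two-item average midway between
  "mild" (2,2) and "moderate" (3,3) item scores — i.e. the top of the
  sub-moderate band. It is explicitly a configurable convention, not an
  estimated quantity;
* `time_below_threshold` accumulates grid intervals whose right endpoint
  is sub-threshold; `relapse_time` is the first grid time at or after the
  final planned session with severity at or above the threshold (an
  untreated severe patient relapses at day 0 by this convention);
* the default grid step of 0.25 days resolves crossing times to
  six hours.

`compare_plans()` ranks candidates: no relapse is best, then later
relapse, then more time below threshold, with ties going to the plan with
fewer sessions. Planning normally uses a patient's empirical-Bayes
parameters; planning from the typical values is available for
unclassifiable patients (the `--use-typical` CLI flag) and should be
labelled as such when shown to clinicians.

## The synthetic cohort generator

Real records of this kind are protected clinical data, so the generator
reproduces their *structure*, letting every other module be exercised
end-to-end without any download:

* every patient enters severe (severity 1 at day 0);
* reports are requested every 30 or 60 days (equal mixture by default)
  with 3 days of Gaussian timing jitter, and each request is completed
  with probability 0.6 — so realised report counts are sparse (typically
  4–9 per patient) despite regular scheduling;
* follow-up is uniform on 180–720 days;
* sessions arrive as Poisson streams per service, calibrated so a
  450-day follow-up yields about 1.7 coaching, 16 therapy and 3.5
  psychiatry sessions on average; a shared log-normal per-patient
  engagement factor (SD 0.4) scales all three rates, inducing the
  positive therapy–psychiatry utilisation correlation seen in real
  cohorts;
* five archetypes shape the schedule: sustained cadence (`response`,
  `saturated`), cadence then a terminal gap of at least 90 days
  (`rebound`), cadence–gap–re-engagement (`multiphasic`), and sparse
  irregular care (`poor_fit`), whose observations additionally receive a
  random-walk disturbance so that the schedule genuinely fails to explain
  them;
* observed severities are the model trajectory under the patient's true
  parameters plus Gaussian noise, snapped to the 0.125 grid of the
  two-item score and clamped to $[0,1]$ (both optional);
* any draw violating the inclusion rule — at least two reports with at
  least one session in between — is resampled, so emitted cohorts are
  100% eligible, and the ground truth (archetype, engagement, true
  parameters) is returned as a ledger for recovery testing.

The default generating population is the package's engineering-default
typical values with $\omega = 0.3$ on all five log-scale parameters and
$\sigma = 0.1$ severity units — moderate between-subject variability and
residual noise chosen once as plausible for sparse self-report data; no
published parameter values exist for this kind of model, and these
defaults are explicitly not estimates.

What the generator does *not* emulate: informative timing (real patients
report and attend more when unwell), covariates, co-occurring symptom
dimensions, item-level response styles, drop-out that correlates with
severity, and drift of individual parameters over time. Passing recovery
and triage tests on synthetic cohorts therefore demonstrates internal
consistency of the estimator and the pipeline — not that the model is
adequate for any particular clinic's data.

## What the checks compute, and at what sizes

The package's property checks are chosen to be independent of the code
paths they test: analytic limits (zero treatment, forced full inhibition,
constant mass), the quadrature oracle above, an exhaustive re-statement of
the triage rule table on a $61\times 61$ grid including boundary points,
monotonicity sweeps (an added session never increases later severity; a
denser plan never spends less time below threshold, to one grid step),
and parameter recovery on self-generated cohorts. The replicated recovery
study uses ten 300-patient cohorts at the generator defaults, each fitted
with an equal 200+200 exploration/smoothing split (the single-cohort run
in the reproduction script uses 300+300); the archetype check fits a single mixed cohort and
requires `poor_fit` patients to be flagged (semi-supported or unsupported)
more often than `response` patients; determinism is checked by comparing
artifacts byte-for-byte across repeated runs. These sizes are the
package's own choices balancing statistical resolution against a
practical desk-scale runtime.

## Known limitations

* Weakly utilised services (coaching and psychiatry average a handful of
  sessions per patient) leave their $k_{out}$ with wide sampling scatter;
  population estimates of those parameters should be read with that in
  mind.
* The additive Gaussian error treats the discrete 0.125-grid severities
  as continuous; near the boundaries (0 and 1) the error is censored, and
  fits are known to over-predict the lowest severities.
* Diagnostics are trace-based; no standard errors are reported
  (bootstrap and likelihood-profile machinery are out of scope).
* The triage thresholds are practical initial values; optimising them
  against specific clinical outcomes is future work, and the
  worst-of-grades combination rule is intentionally conservative.
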