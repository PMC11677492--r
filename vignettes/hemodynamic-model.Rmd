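---
title: "A population turn-over model of propofol and remifentanil hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population turn-over model of propofol and remifentanil hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemopd)
```

## The model

`hemopd` models the time course of mean arterial pressure (MAP, mmHg) and
heart rate (HR, bpm) during propofol/remifentanil anesthesia with surgical
stimulation.  Both responses follow indirect-response ("turn-over")
dynamics: each is maintained by a zero-order input and removed by
first-order loss,

$$\frac{d\,MAP}{dt} = k_{in,MAP}\,\bigl(1 - f(C_{Propo})\bigr)\,
  \bigl(1 - g_{MAP}(C_{Remi})\bigr)\, p(HR)\, h(Stim) - k_{out,MAP}\,MAP,$$

$$\frac{d\,HR}{dt} = k_{in,HR}\,\bigl(1 - g_{HR}(C_{Remi})\bigr)\, q(MAP)
  - k_{out,HR}\,HR,$$

with the steady-state constraint $k_{in,i} = k_{out,i} \times
\text{baseline}_i$, so the system starts and (absent perturbation) stays
at $(MAP_0, HR_0)$.  Drug effects are inhibitory sigmoid-Emax functions of
the *predicted plasma* concentrations,

$$f(C) = \frac{E_{max}\,C^{\gamma}}{C^{\gamma} + C_{50}^{\gamma}},$$

heart rate feeds back on the MAP input as $p(HR) = (HR/HR_0)^{FB_{HR}}$
(a proxy for the cardiac-output contribution of HR), and a noxious
surgical stimulus transiently raises the MAP input by the factor
$h(t) = 1 + \theta_{Stim}\, e^{-k_{Stim}(t - t_{Stim})}$ for $t \ge
t_{Stim}$ (equal to 1 before onset, peaking at $1 + \theta_{Stim}$ at
onset).

In the reduced **final model** the remifentanil effect acts on HR only
(and reaches MAP indirectly through the feedback), the MAP-on-HR feedback
is absent ($FB_{MAP} = 0$), the propofol Hill coefficient is fixed at 1,
only the surgical stimulus (hysteroscopy) has an identified effect, and
the pharmacodynamics are driven by plasma rather than effect-site
concentrations.  `model_config()` retains all four structural switches so
the richer base model can be simulated and compared; neutral switch
values reproduce the final model bit-for-bit.

Concentrations come from the standard three-compartment models with
covariate adjustment: Schnider (propofol, with the effect-site rate
constant $k_{e0}$ fixed at 0.456 min$^{-1}$, the value programmed in the
study pumps) and Minto (remifentanil, age-adjusted $k_{e0}$), both using
the James lean-body-mass equation.  Target-controlled infusion (TCI) is
reproduced with a 10-s pump update: plasma mode solves each interval's
rate exactly; effect-site mode uses the standard burst/coast/maintain
logic, root-finding the burst rate on an analytic (eigendecomposition)
prediction of the future effect-site peak so the target is reached
quickly without sustained overshoot.

## Parameters

Defaults throughout are the final-model population estimates:

| parameter | value | units | meaning |
|---|---|---|---|
| $MAP_0$, $HR_0$ | 88.2, 70.8 | mmHg, bpm | baselines (IIV 8.63%, 14.4%) |
| $k_{out}$ | 0.123 | min$^{-1}$ | loss rate, shared typical value; IIV 142.6% (MAP), 130.2% (HR) |
| $C_{50,Propo}$, $E_{max,Propo}$ | 8.79, 0.88 | µg/mL, – | propofol inhibition of the MAP input (IIV on $C_{50}$ 104%) |
| $C_{50,Remi}$, $E_{max,Remi}$, $\gamma_{Remi}$ | 4.57, 0.69, 1.20 | ng/mL, –, – | remifentanil inhibition of the HR input (IIV on $C_{50}$ 103.7%) |
| $FB_{HR}$ | 0.806 | – | HR-on-MAP feedback exponent |
| $\theta_{Stim}$, $k_{Stim}$ | 0.284, 0.021 | –, min$^{-1}$ | stimulus impact and dissipation (half-life $\ln 2 / k_{Stim} \approx 33$ min) |
| $\sigma_{MAP}$, $\sigma_{HR}$ | 5.53, 4.30 | mmHg, bpm | additive residual SDs |

The derived inputs are $k_{in,MAP} = 10.8$ mmHg·min$^{-1}$ and $k_{in,HR}
= 8.7$ bpm·min$^{-1}$.

Inter-individual variability is log-normal (`typical`·$e^\eta$) for all
dispersed parameters; the $E_{max}$ parameters, when given variability,
use a logistic transform centred at logit(typical) so samples stay in
(0, 1) — the centring choice is ours, the source analysis states only the
constraint mechanism.  The $C_{50,Propo}$ and $k_{out,MAP}$ random
effects share a covariance of 0.76 (correlation ≈ 0.84).  The variance of
the stimulus-dissipation random effect is fixed at $\ln 2$, the value
equivalent to a 100% CV, because it is not stably estimable.

```{r params}
p <- hemo_params()
derive_kin(p)
effect_propofol(8.79, p)      # half-maximal inhibition: 0.44
log(2) / p$k_stim             # stimulus dissipation half-life (min)
```

## Numerical choices

The turn-over system is small and non-stiff; rather than an adaptive
solver we use two fixed-grid integrators on the 10-s concentration grid,
with drug inputs interpolated linearly between nodes:

* **RK4 with substeps** (`method = "rk4"`, the default and the reference
  path): valid for every configuration.  Stimulus onsets are aligned to
  step boundaries (activity is decided at the start of each substep), so
  the onset discontinuity never falls inside a step; against closed-form
  linear solutions the error is below $10^{-12}$ relative, and against
  `deSolve::lsoda` at rtol $10^{-10}$ below $10^{-3}$ (the difference is
  dominated by how lsoda smooths the onset jump).
* **Exact exponential-integrator cascade** (`method = "exact"`, used
  inside the estimation core): with no MAP-on-HR feedback the HR equation
  is autonomous and both equations are linear first-order ODEs with a
  time-varying source; each step is propagated exactly for a piecewise
  linear source.  It is ~6× faster than RK4 and agrees with it to
  ~$2\times10^{-4}$ relative; the residual difference is source-curvature
  within a grid interval, far below the residual error.

PK propagation is exact for piecewise-constant infusion (augmented-matrix
exponentials), which also handles the zero-clearance mass-balance case.

## Estimation

`fit_hemodynamics()` maximizes a Laplace approximation of the marginal
likelihood: for each subject the 7 random effects are fitted by a
penalized Gauss-Newton (finite-difference Jacobian, line search), and the
subject's contribution is evaluated at that mode with the Gauss-Newton
Hessian.  With additive residual error this is a close surrogate for
first-order conditional estimation (the interaction term vanishes).  The
outer problem runs `nlminb` on transformed scales — log for positive
parameters, logit for the $E_{max}$, a scaled logit keeping
$\gamma_{Remi}$ in [0.5, 5] (an identifiability guardrail), atanh for the
correlation — with a forward-difference gradient whose step ($10^{-3}$ on
the transformed scale) is chosen to dominate the small noise left by the
warm-started inner optimizations.  Per-subject modes are warm-started
across outer evaluations.  The pharmacodynamic grid inside the fit is
thinned to 20-s steps (`control$thin = 2`); the response time constants
(minutes) make the added discretization error negligible against
$\sigma$.

Standard errors (`se = TRUE`) come from a finite-difference Hessian of
the marginal $-2\log L$ with delta-method back-transformation; they are a
different estimator than a covariance-step from a specific FOCE
implementation, so only rough agreement with published RSEs should be
expected.  Percentile bootstrap CIs (`bootstrap_hemo()`, subject-level
resampling, warm-started refits, order-statistic percentiles) are the
preferred uncertainty summary.

Estimating the MAP-on-HR feedback is not supported in the fit (the final
model excludes it and the fast cascade requires an autonomous HR
equation); the base-model remifentanil-on-MAP effect and the propofol
Hill coefficient can be freed via `model_config()`.

## The synthetic study

Real observations are unavailable, so `generate_dataset()` emulates the
study design: four groups (A propofol only, B remifentanil only, C stable
propofol + varying remifentanil, D stable remifentanil + varying
propofol) with 25-min step-up / 15-min step-down effect-site target
schedules, every level held at least 5 min; MAP/HR observed every minute
(with pre-dose baselines), infusion rates recorded every 10 s; a
hysteroscopy stimulus after the step-down phase for groups A/C/D.  The
appendix-level per-scheme target ladders are not published, so we
generate configurable ladders spanning 1–8 µg/mL (propofol) and 1–8
ng/mL (remifentanil) — the ranges implied by the estimated $C_{50}$s;
what matters for estimation is the informativeness of the perturbation,
not the exact levels.  Subjects share the typical demographic profile
(female, 43 y, 62 kg, 161 cm) because the model carries no
pharmacokinetic inter-individual variability; groups A/C/D are annotated
as hysteroscopy (training) and group B as other procedures (test),
emulating the 56/21 split at n = 77.

Not emulated: the clinical contingencies (BIS-based lockouts, repeated
LMA attempts, rescue titration), censoring after vasoactive drugs,
circadian baseline variation, and BIS/motor responses.  Passing tests on
these data therefore demonstrate parameter recovery and diagnostic
calibration *under the model*, not robustness to protocol deviations
present in real records.

A note on windows used in the risk summary: the per-minute risk at
exactly the 20-min stimulus onset still reflects the pre-surgical state
(the stimulus has had no time to act), so `summarize_max_risk()` assigns
minutes 0–19 to the pre-surgery window and minutes 21–90 to the
surgery-and-after window by default.

## Problem sizes used in the checks

The package's own test suite runs the full pipeline at sizes chosen to
exercise every claim while staying desk-scale: hypotension risk at the
study's 1000 replicates per scheme; parameter recovery on five replicate
56-subject studies (medians reported); pcVPC calibration with 200
simulated datasets on a 20-subject study; bootstrap behavior with
warm-started refits at reduced replicate counts; the LRT null-calibration
at a restricted-parameter scale (20 replicate fit pairs).  The VPC and
bootstrap defaults remain 500, the analysis-scale values.

## Known limitations

* The marginal likelihood is a Laplace approximation; exact FOCE-I
  objective values are not reproduced, so $-2\log L$ differences should
  only be compared within this package.
* Population weighted residuals are residual-SD-scaled, not
  FOCE-linearized (no exact CWRES).
* The stimulus model is a single mono-exponential decay per event with no
  off-switch at surgery end; multiple events compose multiplicatively.
* TCI reproduces the discrete 10-s update logic, not any particular pump
  firmware; rates are not constrained by syringe limits.
* Covariate effects on pharmacodynamic parameters are not modelled (none
  were retained in the source analysis).
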