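---
title: "Methods: the osteodyn bone remodeling model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the osteodyn bone remodeling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteodyn)
```

## Scope and assumptions

`osteodyn` models bone turnover in a single well-mixed basic
multicellular unit (BMU). Five cell populations — preosteoblasts (PB),
osteoblasts (B), preosteoclasts (PC), osteoclasts (C), and osteocytes
(S) — interact with one signaling molecule, sclerostin (Sc), and drive
one output variable, bone density (Bd). All states are dimensionless:
PC and C are scaled by the BMU's daily preosteoclast production, the
remaining cells and sclerostin by the daily preosteoblast production,
and estrogen by its level at menopause onset. Under that scaling both
precursor pools have basal production exactly 1.

Three modeling assumptions matter most:

* **Estrogen is algebraic, not a state.** Its trajectory is imposed:
  constant 1 before onset `t_m`, then either a hyperbolic decay with
  characteristic time `tau_E` (natural menopause) or an exponential
  collapse to the plateau `k_syn / kappa_E` (surgical menopause,
  clearance vs residual synthesis). Nothing feeds back into estrogen.
* **Sclerostin lumps the signaling network.** Wnt inhibition and
  RANKL-mediated osteoclastogenesis are not explicit species; their
  net effects are carried by sclerostin's Hill-type action on
  osteoblastogenesis (inhibition), osteoclastogenesis (activation),
  and bone formation (inhibition). Osteocytes are sclerostin's only
  source, and estrogen inhibits its production.
* **Surgery acts through two transient rate boosts.** At onset,
  osteocyte apoptosis is multiplied by `1 + eta_surg exp(-tau (t -
  t_m))` and preosteoclast-to-osteoclast differentiation by `1 +
  omega_surg exp(-tau (t - t_m))`, sharing one relaxation rate `tau`;
  `tau = 0` makes both permanent. These stand in for the inflammatory
  and metabolic response to surgery, which the model does not resolve
  mechanistically.

Mechanical strain sensing by osteocytes, pharmacological treatments,
and explicit RANKL/OPG/Wnt dynamics are deliberately out of scope.

## Parameters

All rates are per day; the estrogen decline time `tau_E` is accepted
in years and converted on ingestion (`$tau_E_days`), and user-facing
trajectory output reports years since onset. The packaged defaults
(also shipped as flat JSON under `inst/extdata/parameters/`) are the
published parameterization of the natural-menopause model plus the
surgical estrogen kinetics:

* Turnover rates: `omega_PC = 0.93`, `omega_PB = 0.32`,
  `omega_B = 6.4e-4`, `eta_B = 8.678e-3`, `eta_C = 1.096e-4`,
  `eta_S = 1.1e-4`, `kappa_Sc = 0.05` (day^-1).
* Bone turnover: `lambda_B = 1.29e-6`, `lambda_C = 3.82e-6` (day^-1),
  formation modulated by sclerostin (`sc_Omega = 3.04e3`) and coupled
  to resorption (`nu_Omega = 1.08e3`, `r_Omega = 1.02e3`);
  `BMC0 = 0.8` converts density to BMD.
* Estrogen thresholds: `e_PC = 0.2556`, `e_Sc = 10.59`; sclerostin
  thresholds `sc_PC = 8.6e6`, `sc_PB = 1.63e2`.
* Surgical kinetics: `kappa_E = ln 2 / (161 min) = 6.1996` day^-1 and
  `k_syn = kappa_E * 15/156 = 0.596` day^-1, derived by
  `estrogen_kinetics_from_physiology()` from the post-menopausal
  estradiol half-life and the serum drop from 156 to 15 pg/mL by 30
  days after surgery.
* Surgery-effect presets: `surgical_preset("short_term")` gives
  `{eta_surg = 5, tau = 9.7e-3, omega_surg = 1.86}` (calibration
  against data up to 15 years) and `surgical_preset("long_term")`
  gives `{eta_surg = 0.4174, tau = 0, omega_surg = 0.2155}` (up to 30
  years, permanent effects).

## Steady-state initialization

Simulations start 30 years before onset from the equilibrium of the
six cell/signal equations at the starting estrogen level, with Bd
fixed at 1. The system is triangular at steady state, so
`premenopausal_steady_state()` solves it in closed form
(B → S → Sc → PB, PC; C = 1/eta_C) and, by default, cross-checks the
answer with a Levenberg–Marquardt root solve in log space started from
a 25% perturbation; the two must agree to 1e-10 relative. The closed
form removes any dependence on root-solver behavior; the numerical
solve remains purely as verification. Because the fitted thresholds
enter the equilibrium, the calibration routines recompute it for every
trial parameter vector.

One structural fact deserves emphasis: at equilibrium the osteoclast
influx is pinned to 1 by the preosteoclast balance, so `C = 1/eta_C =
9124` under the default `eta_C = 1.096e-4`. Reference tabulations for
this parameterization quote an initial osteoclast level of about 42,
which no solution of the printed equations can produce with the
printed `eta_C`; the package follows the equations and flags the
discrepancy (`verbose = TRUE`).

## The formation–resorption imbalance under the default constants

Evaluating the bone density equation at the default premenopausal
equilibrium gives formation `0.0283`/day against resorption
`lambda_C / eta_C = 0.0349`/day — a net drift of about `-0.0065`/day,
i.e. hundreds of percent per year, rather than the sub-percent annual
premenopausal loss such models aim to represent. Restoring balance
would require the equilibrium sclerostin level to sit roughly 24%
lower than the printed thresholds and rates imply, which is outside
what rounding of the published constants can explain. Two consequences
for users:

* Integrated over 30 premenopausal years, Bd reaches a large negative
  value at onset, so the *onset-normalized* BMD ratio has a negative
  denominator and reverses every directional comparison. The ratio is
  still computed exactly as defined (it is what the calibration
  objective uses, and it equals 1 at onset by construction), but the
  package's own qualitative regime checks are asserted on absolute
  BMD = `BMC0 * Bd`, where the expected orderings hold: abrupt
  estrogen loss accelerates early loss relative to the natural
  decline; without new cell effects the model overshoots late-time
  loss; the long-term calibration's loss slows markedly at late times.
* The steady-rate sweep (`sclerostin_production_sweep()`) is monotone
  decreasing and crosses zero exactly once on the multiplier range
  `[0.7, 1.2]`, at about 76% of premenopausal sclerostin production
  under the default constants — qualitatively the advertised regime
  (production below a premenopausal fraction yields net formation),
  but the crossing location and the absolute rates (≈ −238 %/yr at
  E = 1, ≈ −303 %/yr at the post-surgical plateau) inherit the
  imbalance and should be read as ordering/sign information only.

The cell-population side of the model is unaffected by this: osteocyte
dynamics under the short-term preset dip to ≈ 94.7% of premenopause
and recover, and under the long-term preset decline permanently to
≈ 78% by 25 years — the mechanism by which reduced sclerostin
production slows late bone loss.

Relatedly, the bone density equation's formation term is implemented
with the resorption factor R = C *enhancing* formation,
`(1 + nu_Omega f+(R, r_Omega))`, which reads naturally as
resorption-coupled remodeling. An alternative inhibitory coupling
`(1 + nu_Omega f-(R, r_Omega))` is exposed via
`natural_parameters(resorption_coupling = "inhibition")` for
exploration; it is not the default and does not restore balance
either.

## Numerical choices

* **Time unit** is days everywhere internally; the mixed year/day
  conventions of the source material are resolved at the boundaries
  (`tau_E` in years on input, trajectory output in years since onset).
* **Integration** uses deSolve's adaptive Dormand–Prince 4(5) pair
  with absolute and relative tolerances of 1e-8, split into a
  pre-onset and a post-onset segment so the discontinuity in E(t),
  omega(t), and eta(t) falls on a segment boundary instead of inside
  an adaptive step. Point evaluations at exactly `t_m` use the
  pre-menopause branch (the laws are defined with `t <= t_m`); the
  post-onset segment integrates the right-limit branch from `t_m`
  onward. The suite verifies the solver against an independent
  fixed-step classical RK4 oracle at h = 0.25 day (relative error
  < 1e-5 over 5 years) and checks tolerance-halving stability
  (< 1e-6).
* **Interpolation** of relative BMD at observation times uses
  monotone cubic (Fritsch–Carlson) splines, so interpolants never
  overshoot the bracketing grid values; the default output grid is
  monthly and is deliberately decoupled from observation times.
* **Calibration** minimizes the unweighted sum of squared residuals
  between model and observed onset-normalized BMD with
  bound-constrained Levenberg–Marquardt (minpack.lm), tolerances 1e-8,
  at most 10,000 evaluations. Integration failures at a trial point
  return large penalty residuals with a warning rather than aborting.
  Estimates within 1e-8 of a bound are flagged `at_bound` (both
  presets sit on a bound: short-term `eta_surg = 5` at the upper,
  long-term `tau = 0` at the lower). RMSE is reported on normalized
  BMD × 100 (percent).
* **Bounds.** The surgery-effect box is `[0, 5]` for both
  fold-increases ("no effect" to "six-fold peak") and `[0, tau_upper]`
  for `tau`. The default `tau_upper = 1` day^-1 caps the effect
  duration at a minimum of about one day; a stricter year-scale cap
  (`1/365` day^-1) is available via `tau_upper`, but it would exclude
  the short-term preset's `tau = 9.7e-3`, so it is not the default.
* **Starting points** are not part of the published procedure, so both
  options are exposed: the default start is the midpoint of the box
  (surgical protocol) or the current parameter values (natural
  protocol), and `multi_start = TRUE` runs a seeded Latin-hypercube of
  starts and keeps the best optimum.

## Data curation

`normalize_study()` divides each study's means and SDs by the
observation nearest onset (which must fall within a configurable
window, default 1 year), preserving each point's coefficient of
variation; the pipeline is idempotent and scale-invariant.
`aggregate_bmd()` pools studies in 1-year bins (configurable) with a
cohort-size-weighted mean and a pooled SD containing both
within-study and between-study components — cohort sizes in published
tables differ by more than tenfold, so equal weighting (available via
`weighted = FALSE`) would let small studies dominate.
`linear_loss_rate()` fits the descriptive OLS slope over the first 15
years; it is a diagnostic only and feeds nothing downstream.

## Synthetic cohorts: what they emulate and what they do not

The generator (`synthetic_cohort_spec()`, `generate_cohort()`) mimics
the structure of cross-sectional DXA study tables: observation times
`{0, 1, 2, 3, 5, 8, 10, 12, 15, 20, 25, 30}` years after onset,
Gaussian noise on normalized BMD with SD 0.05 (the scale of published
error bars), study means drawn with standard error `noise_sd /
sqrt(n)` around the model's own trajectory, cohort size 100 per point
(typical of the published study range of tens to hundreds), five
studies per cohort, and a random per-study raw baseline so generated
tables genuinely exercise the normalization step. Draws are
independent across time points (cross-sectional design); there is no
within-woman longitudinal correlation, no skeletal-site effect, no
age-at-surgery covariate, and — importantly — the "data" follow the
model's own BMD trajectory, including the drift described above, not
the shape of real clinical series. Passing recovery tests therefore
demonstrates that the estimation machinery identifies the
surgery-effect parameters from data with the assumed error structure;
it does not validate the model against real cohorts.

Test problem sizes were chosen to keep the suite fast while remaining
informative: unit-level fits free one parameter over an 8-year
horizon with six observation times; the end-to-end recovery
experiments use the full three-parameter short-term truth over 15
years, noise-free (recovery < 1% relative) and at noise SD 0.02 with
a fixed seed (`eta_surg`, `omega_surg` within 25%). The Monte-Carlo
check of the noise model uses 200 replicate studies at a single time
point.

## Known limitations

* The default constants do not balance formation and resorption at
  the premenopausal equilibrium (see above); absolute and
  onset-normalized BMD levels from long simulations should be
  interpreted with that in mind.
* No mechanics: strain-mediated osteocyte signaling, a known
  sclerostin regulator, is absent.
* No treatments: anti-resorptives, anti-sclerostin antibodies, and
  hormone replacement are not modeled.
* Estrogen is exogenous; perimenopausal variability and individual
  hormone trajectories are outside the model.
* The surgery-effect parameters share one relaxation timescale by
  construction; the data used for the presets cannot separate two.
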