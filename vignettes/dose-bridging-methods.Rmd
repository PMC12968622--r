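---
title: "Model-based dose bridging for empagliflozin in children: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based dose bridging for empagliflozin in children: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empbridge)
```

## The problem

Empagliflozin is established therapy for adult heart failure but has no
paediatric dose. Running a dose-finding trial in children with a rare
condition is neither feasible nor ethical, so the dose rationale has to be
built by *exposure matching*: choose, for each body weight, the fixed tablet
strength (10 or 25 mg once daily) whose predicted exposure in a child falls
inside the exposure window observed in adults. `empbridge` implements the
full workflow: an adult population-pharmacokinetic model, allometric
extrapolation to paediatric weights, virtual-cohort simulation of exposure
ratios, the minimum-admissible-weight decision rule, and the design of the
confirmatory sparse-sampling study (Fisher-information D-optimality plus
simulation–re-estimation).

## Structural model

Disposition follows a two-compartment model with first-order elimination and
sequential zero-/first-order absorption: the dose enters a depot at a
constant rate over `d1` hours, delayed by a lag `alag1`, and transfers to
the central compartment at rate `ka`. All parameters are apparent oral
quantities (CL/F, Vc/F, Vp/F, Q/F), i.e. bioavailability is folded in. Doses
in mg are converted to nmol with a molar mass of 450.91 g/mol because
exposures are reported in nmol·h/L.

The solver is the exact closed-form piecewise superposition of the linear
system (partial-fraction decomposition over the three exponentials), not a
numerical integrator. Two consequences matter for testing: the model is
*exactly* linear in dose, and the steady-state AUC over one interval equals
dose/CL to machine precision up to grid error. The test suite verifies the
solver against an independent stiff ODE integration (`deSolve::lsoda`,
relative tolerance 1e-10) and against closed-form accumulation factors in
the one-compartment limit. For uniform once-daily dosing the superposition
over past doses is evaluated by an exact geometric series, so cost does not
grow with treatment duration.

Numerical edge cases are handled explicitly: near-equal disposition
exponents and `ka` colliding with an exponent are separated by a relative
nudge of 1e-8; `q_f` or `vp_f` below 1e-8 of their scale collapse to the
one-compartment formulas (this also defines the terminal half-life in the
`q_f -> 0` limit, where the nominally smaller exponent has vanishing
amplitude); `d1 -> 0` switches to the bolus-into-depot limit.

## Allometric extrapolation and the virtual cohort

Clearances scale as `(W/70)^0.75` and volumes as `(W/70)^1.0`; absorption
parameters are weight-independent. The exponents are configurable because
the reported exposure table is slightly better reproduced by a flow exponent
near 0.79, but the conventional theory-based 0.75 is the default and all
reported checks pass with it.

Inter-individual variability is lognormal and diagonal on CL/F, Vp/F, Q/F,
D1, ka and ALAG1 (the central volume carries none, matching the random-effect
structure of the adult reference model). Residual error is proportional.
The trial cohort draws weights from a truncated normal, 38.1 ± 16.8 kg on
[15, 90] kg, by inverse-CDF sampling (reproducible and exactly bounded); the
dose-rationale grid instead spans 10–90 kg at fixed weights. A five-patient
clinical survey (weight median 42 kg, IQR 27–44) can be resampled through a
quantile-matched lognormal: the log-median is log(42) and the log-SD is the
least-squares fit to the two printed quartiles — the only summaries
available.

## The calibrated reference fixture

The adult model's published typical values are not reprinted in any input
available to this package, so `make_reference_parameters()` builds a
calibrated stand-in, and every value can be overridden:

* CL/F comes from the AUC identity: 25 mg (55,444 nmol) over a typical
  steady-state AUC of 5,499 nmol·h/L gives 10.08 L/h — this is exact, not
  fitted.
* `alag1` is fixed at 0.3 h; `vc_f`, `vp_f`, `q_f`, `ka`, `d1` are found by
  a Nelder-Mead search from a fixed starting point (hence deterministic and
  idempotent) driving three anchors to zero miss: Cmax 766.5 nmol/L,
  Tmax 1.4 h, terminal half-life 9 h (the centre of the reported 7–12 h).
  The search has more parameters than anchors; the fixed start selects one
  well-behaved solution, which is then frozen by determinism.
* ω²(CL) = (log(6398/4696) / (2·qnorm(0.75)))² ≈ 0.053 (23% CV) follows
  from the AUC interquartile anchor, since AUC = dose/CL is lognormal.
* The remaining ω² default to 0.09 (30% CV) and σ to 0.15. These are
  documented placeholders at magnitudes conventional for oral PK, chosen to
  reproduce the reported ratio-IQR widths; they are not published estimates.

The fixture constructor re-verifies all anchors at build time and fails,
naming the violated anchor, if an override makes them unreachable.

## Exposure matching and the weight cut-off

For a child weight and dose, `ratio_distribution()` simulates independent
child and adult virtual subjects (variability on both sides) and summarises
per-pair ratios of steady-state AUC(0–24), Cmax and Css. Independent pairs —
rather than common random numbers — are intentional: the ratio spread then
reflects two independently sampled populations, which is what a ratio of
empirical distributions would show.

The decision rule in `evaluate_weight_bands()` flags a (weight, dose) cell
as admissible when the *median* AUC ratio against a normal-weight adult on
10 mg is ≥ 0.70 (efficacy floor) and the median AUC and Cmax ratios against
the 50 kg adult on 25 mg are ≤ 1.30 (safety cap). Medians are compared
against the limits because that is how the reference quantities are
reported; the full quantile set (5/25/50/75/95) and the safety reference's
own 95th percentile are emitted alongside so stricter rules can be applied
downstream. The safety comparator defaults to the 50 kg adult and is
configurable to 70 kg. On the 10–90 kg grid at 10 mg the rule yields a
minimum admissible weight of 15 kg, stable across seeds at 10,000 subjects
per cell.

Because AUC at steady state is dose/CL exactly, AUC ratios use the analytic
identity; Cmax and Tmax are read off a 0.05 h grid over one interval with
ties broken to the earliest time. Grid error is far below the reported
precision, and a grid maximum cannot overshoot.

## Expected Fisher information and design optimisation

Design evaluation uses the standard first-order (FO) population-design
approximation. For one subject with schedule `t`: the mean is the prediction
at the typical parameters; the covariance is `G Ω G' + σ² diag(f²)` with `G`
the finite-difference sensitivity (relative step 1e-4) to the log-scale
random effects at η = 0. The FIM is block-diagonal between fixed effects and
variance parameters (ω², σ²), the usual population-design practice. The
fixed-effect block is computed on the log scale, which makes both the
D-criterion and %RSE invariant to parameter units — verified in the tests by
reparameterising the same model at a different reference weight.

`optimise_schedule()` maximises the log-determinant under the clinical
constraints: at most 6 samples within the 8 h first-dose stay, one sample
21–27 h after the week-1 dose, an optional week-3 sample in half the groups,
and times rounded to a 6-minute grid. The optimiser is multistart coordinate
descent: each coordinate is scanned over its full rounded window, so the
result is a grid-local optimum; the empirical 0.5/1/2/4/6/8/168 h scheme is
always included as a start, which guarantees the optimised criterion never
falls below the empirical one. Per-group information blocks are cached so a
candidate move re-evaluates only one group.

## Simulation–re-estimation

`run_sse()` simulates replicate trials under a scenario (weights, IIV,
proportional noise truncated at zero), refits the model to each, and
summarises estimated/true ratios against the 0.7–1.3 acceptability band.
Replicate seeds derive deterministically from the base seed, making the
whole study bitwise reproducible.

The estimator is Laplace-approximate maximum likelihood (FOCE-like): per
subject the random-effect mode is found by a damped Newton search using an
analytic gradient and a Hessian that keeps all Jacobian-level terms of the
proportional-error model (dropping only second derivatives of the
prediction); the marginal likelihood adds the log-determinant of the
Gauss-Newton curvature at the mode. The inner search always starts from a
fixed per-subject point — the empirical-Bayes mode under the initial
parameter values, itself seeded by a data-driven heuristic (η_CL from the
overall observed/predicted exposure offset, shrunk and clamped). Because
that start is a constant of the fit, the outer objective is a *pure
function* of the parameters; warm starts that carry state between
evaluations were tried and rejected because they make finite-difference
outer gradients inconsistent and stall the optimiser, while the fixed
near-mode start keeps evaluations close to the initial values cheap.
The outer optimiser is `nlminb` with an explicit central-difference gradient
at step 1e-3 on the log-parameters: the likelihood surface is slightly
rough (near-degenerate inner modes can flip under tiny parameter changes,
a known feature of Laplace objectives with absorption-lag kinks), so the
difference step must dominate that roughness, which a
machine-epsilon-sized internal step would not. A stopped fit is accepted
only if a coordinate probe (step 0.02 on the log-parameters) finds no
remaining descent beyond 0.5 OFV units — the likelihood-ratio scale at
which parameter movement becomes comparable to sampling uncertainty;
otherwise the fit restarts from the probe's improved point, up to three
times, before being reported as non-converged. One consequence of this
resolution-limited convergence, combined with initialising re-estimation
at the simulation values (the convention when the fitted model is the
data-generating model), is that replicate-to-replicate spread on very rich
designs partially understates the estimator's sampling variability: a fit
whose optimum lies within the resolution of its starting point never needs
to move. Non-converged replicates
are excluded and counted; more than 20% failures flags the result unusable.

Fixed effects are estimated on the log scale and variances on the
log-variance scale (positivity without constraints). By default all seven
fixed effects, ω²(CL) and σ² are estimated while the remaining IIV variances
stay fixed at their initial values: with 12 subjects and 7–8 samples each
those variances are practically unidentifiable, and which ones the original
analysis estimated is not documented — the choice is recorded in the fit
object and fully configurable. Priors are normal penalties on the log fixed
effects; the non-informative mode applies none, and the tests verify both
the prior-dominance limit and convergence of a vague prior to the
non-informative fit. A likelihood floor of 1e-3 nmol/L enters the
proportional-error variance so samples drawn before the absorption lag
cannot produce an infinite objective.

The Laplace approximation is cross-checked against adaptive Gauss–Hermite
quadrature (30 nodes, Golub–Welsch) on one-compartment reductions with a
single random effect, agreeing within 0.5 OFV units. The derived AUC ratio
is computed from the clearance ratio — exact under linear kinetics — rather
than by re-integrating profiles.

## Problem sizes and reproducibility

The package's own checks run at deliberately chosen sizes: 10,000
virtual pairs per exposure-ratio cell (median standard error well under 1%),
100 SSE replicates for the rich (40 × 14) and sparse (12-subject, 4-group)
scenarios, and 10 seeds for the weight cut-off stability check. The
simulation–re-estimation scale of the original analysis (500 replicates) is
available by argument. All randomised entry points take explicit seeds, and
`run_pipeline()` writes every stage's seed and a configuration hash into its
manifest.

## What the synthetic data do and do not show

The virtual cohorts emulate the stated study conditions: parametric weight
distributions, lognormal IIV, proportional noise, and the printed sampling
scenarios. They do not emulate real-data features such as covariate
correlations (weight–age–renal function), model misspecification, dropout,
dosing-history errors, or BMI-driven covariance of disposition parameters.
Passing tests therefore demonstrate that the pipeline implements the stated
model and decision rules faithfully and recovers known truth under its own
assumptions — not that the fixture equals the unpublished adult estimates,
nor that the design conclusions transfer to data the model does not
describe.

## Known limitations

* The fixture is a calibrated stand-in; absolute exposure levels inherit
  its anchor choices, though ratio-based conclusions are insensitive to
  most of them (AUC ratios depend only on dose and the clearance scaling).
* The FO information matrix and the Laplace likelihood are different
  approximations; their precision predictions are compared at a factor-two
  tolerance on the disposition parameters that the re-estimation step
  reports, and they do not always reconcile. The gap is largest for the
  central volume on the rich design: Vc/F carries no random effect, so the
  FO approximation treats all inter-individual variability as unexplained
  noise when propagating its uncertainty, while the conditional (Laplace)
  estimator explains that variability through the random-effect modes and
  determines Vc/F several-fold more precisely than FO predicts. The
  truth-initialised replication spread additionally runs below the
  estimator's true sampling variability on rich designs (see above), so
  the factor-two agreement holds on the sparse 4-group design but fails
  for Vc/F (and marginally Q/F) on the rich 40-subject design.
* The individualised (per-subject) schedule variant is a synthetic
  stand-in, as the original per-subject table is unpublished.
* No ontogeny/maturation function: glucuronidation maturation is treated as
  complete in the ≥ 2-year-old, ≥ 15 kg population of interest.
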