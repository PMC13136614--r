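---
title: "Hybrid digital twins of fed-batch CHO culture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid digital twins of fed-batch CHO culture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`chotwin` builds predictive digital twins of fed-batch Chinese hamster
ovary (CHO) cultures producing a monoclonal antibody. Four modelling layers
are coupled into one simulation engine:

1. **Rate estimation** -- Bayesian ensembles of cell-specific metabolic
   rates from sampled concentrations;
2. **Growth prediction** -- a recurrent neural network for the specific
   growth rate;
3. **Kinetic ODE models** -- the biomass population balance and the five
   "FLEX" metabolites (glucose, lactate, glutamine, glutamate, ammonium);
4. **PC-dFBA** -- a PCA-constrained dynamic flux balance analysis that
   predicts the remaining exchange fluxes and the product titer on a
   reduced metabolic network.

Because no public dataset with this structure exists, a synthetic-data
generator is a first-class module: it produces fed-batch cohorts with
known ground truth so that every layer is testable end to end.

# Units

The single internal unit system is: time in **days**, concentrations in
g/l, cell densities in 1e6 cells/ml, cell-specific rates in
g/1e9 cells/day, reactor volume in ml. The reference kinetic parameter set
(see `kinetic_parameters()`) is interpreted on this per-day base: on a
per-hour base its maintenance glucose coefficient (0.88 g/1e9 cells) would
imply uptake roughly twenty-five times faster than CHO cultures ever show,
whereas per day it sits in the physiological range, and the growth-rate
truncation threshold used by the population model is likewise quoted per
day. Choosing days everywhere removes all boundary conversions; file I/O
is in days as well.

# The synthetic study design

`synthetic_config()` defaults encode the emulated study: 23 batches over 8
media-formulation groups, a 14-day horizon with daily sampling,
inoculation at 0.3e6 cells/ml, combined nutrient feeds (FMA + FMB) daily
from day 3, and glucose stock (FMG, 400 g/l) added from day 5 whenever
glucose falls below 5 g/l. Within a media group, feed compositions are
shared and feed volumes scaled per batch by a uniform factor in
[0.7, 1.3].

The latent dynamics are generated with the package's own kinetic equations
and the reference parameter set, plus a net growth profile that is exactly
a 4-sigmoid sum (amplitudes 0.62/0.10/-0.11/-0.02 per day, scaled
per media group by 0.92--1.08). This makes two classes of tests exact by
construction: parameter re-identification can recover the generating
values, and the growth baseline can recover its own functional form.
Choices the emulated protocol does not fix were set once at realistic
values: initial glucose 18 g/l (so the pre-FMG phase does not deplete),
initial glutamine 4 g/l (so the uptake kinetics sweep through their
half-saturation region, keeping `vGln_max` and `KGln` separately
identifiable), working volume 10 ml with 0.15 ml sampling losses, and a
lognormal multiplicative measurement error with CV 0.05 (the assay noise
magnitude is not documented anywhere; 5% is typical of at-line
analyzers).

Amino acids outside the FLEX panel and the product titer are generated
with a rank-2 structure: each specific rate is a group-specific linear
combination of a constant and a growth-linked component, jittered per
batch along the same two directions. Window-PCA of the cohort therefore
has a known low-rank answer, which is what the loading regressors must
recover. What the generator deliberately omits: pH/DO control, osmolality,
temperature shifts, cell-cycle structure, and any metabolite-metabolite
regulation beyond the encoded rate laws. Passing tests therefore
demonstrate algorithmic correctness, not biological validity on real
cultures.

Samples follow the **pre-feed convention**: the recorded value at a
feeding day is the concentration before that day's additions, and bolus
events are time-stamped an infinitesimal (1e-6 d) after the sample. The
glucose controller sizes each FMG bolus by fixed-point iteration on the
post-feed concentration, anticipating one sampling interval of consumption
at the grown cell density plus a 25% margin -- emulating an operator
keeping glucose above the floor with once-daily additions.

# Rate estimation

`volume_correct()` removes feed-event steps from a measured series; the
step attributed to each event is computed from the measured value at the
preceding sample with that day's boluses applied in stream order, making
raw -> pseudo -> raw reconstruction exact on the sampling grid.
`fit_basis()` then fits sums of 1--3 logistic functions. Slopes are
parameterised on the log scale (amplitudes carry the sign), priors are
weakly informative and scaled to the data range, and the observation noise
includes a quadrature floor of 0.1% of the data range so that noise-free
series remain well-posed. Model order is ranked by a Laplace approximation
of the evidence; a larger basis is accepted only if it gains more than one
nat. Posterior draws come from an affine-invariant ensemble (stretch-move)
sampler seeded at the MAP -- a deliberate, documented substitution for
nested sampling that keeps the same interface and posterior semantics at a
fraction of the cost. Specific rates are the analytic derivatives of
posterior curves divided by paired viable-cell-density draws
(index-matched under a fixed seed); growth rates come from the derivative
of a log-VCD fit. Consumption is negative, production positive,
everywhere in the package.

# Growth network

The predictor is a 4-sigmoid baseline (pooled mean growth across training
batches, Levenberg-Marquardt-polished least squares) plus a dense
deviation network with widths 64-64-64-16-8-1, GeLU activations,
layer normalisation and dropout, implemented from scratch with analytic
backpropagation (gradient-checked against numerical differentiation in
the test suite). The feature vector has `2k + 3` entries for `k`
metabolites -- rates, concentrations, the lagged biomaterial, time and
time step; with the 21-metabolite panel (everything except VCD, glucose,
lactate, ammonium) that is 45 features. The previous predicted growth
rate enters through the biomaterial recurrence
`Xv' = Xv (1 + mu dt)`, `gamma' = gamma + Xv dt`
rather than as a separate input; a naive additive biomass update would be
dimensionally inconsistent with exponential growth, so the multiplicative
first-order form of `dX/dt = mu X` is used.

The loss combines (1) a trajectory- and time-weighted MSE -- trajectory
weights proportional to `1/(|mean(mu_n) - grand mean| + 1e-6)` downweight
outlier posterior draws, time weights `(T - t)/T` emphasise early
dynamics; (2) the absolute difference of time-summed trajectory means;
and (3) the summed absolute second difference of each predicted
trajectory. Training is batch-wise sequential (one optimiser step per
culture per epoch, random order), with the biomaterial teacher-forced
from target trajectories during training and self-fed at inference.
Optimiser details the architecture description leaves open are set to an
adaptive-moment optimiser at learning rate 1e-3 and dropout 0.1, all
configurable, with a mandatory seed; training is bit-reproducible.

# Kinetic ODE models

The population balance tracks viable, dead and lysed cells plus the
cumulative biomaterial `gammaX` (the integral of viable density, a
catch-all for accumulated inhibitory by-products). Death and lysis rates
are base rates plus toxicity terms linear in biomaterial and lysed cells.
Cell balances use a negative dilution term: feeding a fed-batch dilutes
densities, so the dilution term enters with a negative sign. The effective
growth rate is `mu_eff = mu + mu_d + mu_l`, truncated at 1e-6 per day.

The FLEX model uses squared-tanh saturation kinetics, cubic lactate
inhibition of glucose uptake, overflow lactate metabolism (production
when uptake exceeds the oxidative capacity, saturable reuptake otherwise
-- the two branches are mutually exclusive by construction), and ammonium
as a stoichiometric by-product of glutamine/glutamate catabolism.
Ammonium, like lactate, has washout-only dilution. All consumption terms
fade out smoothly as a pool approaches zero (scale 1e-3 g/l); this keeps
states non-negative and the system non-stiff at depletion while changing
the dynamics only within a milligram of exhaustion.

Identification is Nelder-Mead on log-parameters with seeded multi-starts
and a polishing restart. The population fit imposes the measured net
growth on the viable pool and fits the dead-cell trajectory, with a soft
penalty `max(0, |log(Xl/Xd)| - log 3)^2` keeping the unobservable lysed
pool within a factor of three of the dead pool. The FLEX fit imposes
viable-cell dynamics and effective growth and fits all 15 parameters
jointly against the five concentration series. For speed, the FLEX
objective runs on a fixed-step RK4 plan (0.05 d substeps) with
effective-growth/VCD values and affine feed-jump maps precomputed once;
the plan is cross-checked against the adaptive integrator in the tests.
On noise-free cohorts, `mGlc`, `vOx_max` and `vGln_max` are recovered
within 5% from +-30% perturbed starts; `YG`/`KG` are confounded below
glucose saturation and recovered as a ratio, and `KLac`/`YGlu`/`KGlu` are
practically unidentifiable at the lactate and glutamate levels the study
design produces -- a property of the design, not the optimiser.

# Network reduction

The pipeline runs four stages -- demand-reaction feasibility repair,
essential-exchange identification, pFBA-based pruning under all
conditions, and thermodynamically infeasible cycle removal -- each
followed by dead-end/blocked cleanup to a fixpoint, with feasibility and
the growth optimum (1e-6 relative) verified after every stage. Pruning
removes a reaction only when its parsimonious flux is below 1e-9 in
*every* condition and removal provably preserves feasibility and optimum;
cycle removal deletes the lexicographically smallest cycle member whose
removal preserves the optimum, falling back to directionality
restriction. Reactions can be pinned (reinstated with fixed bounds)
regardless of pruning, generalising the reinstatement of biologically
mandatory reactions. Measured-rate constraints enter as 5th/95th
percentile bands of rate ensembles; the conversion from cell-specific
rates to network flux units (mM/gDCW/h) is a single configurable factor,
because the cell-mass conversion is process-specific and not derivable
from first principles.

All constraint-based algebra (FBA, pFBA, FVA, the hybrid program) runs on
a ridge-regularised quadratic-programming core with a two-phase simplex
fallback; the ridge (1e-9) is small enough that solutions sit on the
exact LP vertex, which the tests verify against an independent simplex
implementation.

# PC-dFBA

Loading targets come from PCA of window-mean exchange rates across the
batches of one media group (0.5-d windows, smallest component count
reaching 90% variance, capped at five). One small neural regressor per
component index maps standardized exchange-rate features to standardized
loading vectors; windows lacking a component contribute zero-filled
targets so the output dimensionality is fixed, and the training-fit
standardization constants are reused verbatim at simulation time.
Hyperparameters (hidden units, weight decay) are chosen on a held-out
split from a small seeded grid.

The hybrid program optimises fluxes and PCA scores jointly: mass balance,
global bounds, hard bounds pinning the growth + FLEX subset to predicted
(or measured-mean) rates, the empirical band
`med - RF*iqr <= Se v - Load score <= med + RF*iqr` per measured
exchange, and a score box. Band statistics are medians/IQRs of ensemble
rates over two reliability intervals split at day 3 (the boundary belongs
to the second interval). The objective maximises growth and minimises the
total absolute score through split auxiliary variables, so "least
empirical assistance" is well-defined for signed scores. Defaults the
formulation leaves open: `RF = 1.5`, score box +-100 (generously outside
the training score range), 0.90 variance threshold -- all configurable.
Temporal continuity is lexicographic: the stage-1 optimum is fixed within
1e-6 relative and the squared flux change from the previous step is
minimised as a true quadratic program (an L1 variant is available and
shares the fixed-point property); the first step has no continuity stage.
When pinned hard bounds are infeasible they are relaxed to the 5th/95th
percentile band of the rate distribution. The PC-dFVA diagnostic fixes
the hybrid optimum and min/maximises each exchange, quantifying the
remaining solution-space width.

# The integrated twin

`run_twin()` is fully predictive: from initial concentrations and the
feed schedule alone, each 0.1-d step chains growth prediction, the
kinetic layer (death/lysis, effective growth, FLEX rates), the hybrid LP
(hard-bounded by those predictions), and an explicit-Euler bioreactor
mass balance with bolus feed events that dilute cells and add mass.
Because the growth network needs rates for 21 metabolites that are
themselves twin outputs, the previous step's PC-dFBA fluxes are used (a
one-step lag that breaks the simultaneity of the coupled layers). In
fully predictive mode there are no measurement percentiles, so hard-bound
relaxation widens the predicted pins geometrically (50%, then doubling,
up to six rounds). The empirical band is applied to the dynamically
predicted exchanges only: band statistics for the hard-bounded subset
would re-impose exactly the kinetic rates the pins already carry and can
never be rescued by relaxing the pins. Concentrations are floored at
zero with each flooring event logged. No observation after time zero is
read; the test suite asserts bit-identity of the result when all
later samples are deleted.

On the bundled toy network the hard pins are usually *not* exactly
attainable -- no fixed stoichiometry can track kinetic rate laws whose
by-product ratios drift over time -- so relaxed steps are the norm there,
and the extended toy network carries reversible catch-all interconversion
routes precisely so that the LP retains slack. The genome-scale case has
that slack natively.

# Numerical choices and problem sizes

Adaptive integration uses LSODA at rtol 1e-8 / atol 1e-10 with events
applied between segments. Identification uses 2-batch noise-free cohorts
(150 concentration observations for the FLEX fit), Nelder-Mead budgets of
3000 iterations plus a polishing restart, and one start from the
perturbed initial guess; these sizes keep the full recovery protocol
within a few minutes on one core while leaving the recovery tolerances
comfortably met. The demonstration twin pipeline trains on a 6-batch,
3-group cohort with 20-trajectory growth ensembles and 60 epochs --
deliberately small; the architecture is identical at full scale.
Reduction of a genome-scale reconstruction is supported through the same
API and SBML I/O but is an offline computation, not part of the test
surface.

# Known limitations

Lactate re-accumulation in late culture phases is outside the FLEX model
family, mirroring the acknowledged weakness of the overflow formulation.
The loading regressors consume instantaneous mean exchange rates;
median/IQR summaries would likely generalise better and are a natural
extension. The growth-network feedback loop can amplify concentration
errors late in a prediction -- visible in the demonstration twin as
degraded glucose tracking when predicted growth undershoots. The toy
metabolic network is a fixture, not a CHO model; conclusions about real
cultures require a curated genome-scale reconstruction and measured
data.
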