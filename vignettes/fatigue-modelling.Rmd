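---
title: "Modelling muscle fatigue from wearable speed data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling muscle fatigue from wearable speed data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprintfatigue)
```

## The model and its assumptions

`sprintfatigue` treats an athlete's motor-unit pool as a conserved
capacity `M0` split into three compartments: active (`MA`), fatigued
(`MF`) and available (`MP = M0 - MA - MF`). The driving input is not the
measured movement but the *demanded activation* `MAD(t)` — a step
function describing what the athlete is trying to do. Writing
`dMAD = MAD - MA` for the activation deficit,

$$\frac{dM_A}{dt} = \max(0, \Delta M_{AD})\, M_P\, \alpha_A +
  \min(0, \Delta M_{AD})\, M_A\, \beta_D, \qquad
\frac{dM_F}{dt} = M_A F - M_F R.$$

Activation towards demand is proportional to the available reserve, so a
fresh athlete accelerates quickly and a depleted one cannot;
deactivation is proportional to the active pool itself. Fatigue drains
the active compartment at rate `F` and recovers at rate `R`. Asymmetric
activation/deactivation rates are the essential difference from the
older baseline formulation (`simulate_sns()`), which ties `dMA/dt`
directly to the demand derivative and therefore admits unbounded
activation rates — and, after stepped demand under fatigue, negative
activation (negative implied speed). Both failure modes are reproduced
by the baseline implementation on purpose and contrasted in the test
suite and in the `benchmark` pipeline command.

The working unit is deliberately protocol-dependent. For athletes the
model runs in kinetic energy (J), because converting speed to
`E = ½ m v²` makes efforts comparable across body masses; for the
literature benchmarks it runs directly in the published force (N) or
speed (km/h) scales, with the unit carried as a label. Rate coefficients
are consequently unit-scale-dependent and are never converted between
protocols.

### Capacity convention

The athlete capacity is `compute_m0(mass, vmax)`. Two conventions are
circulating for this quantity: `m·v²max` and the peak kinetic energy
`½·m·v²max`. Since measured efforts are converted with the ½ factor and
`MA` must live on the same scale as measured energy, the package
defaults to `half_mv2` (an 80 kg athlete at 9.14 m/s has
`M0 ≈ 3342 J`, the magnitude of typical calibrated capacities); the
`mv2` convention remains available as a switch on `compute_m0()` and
`athlete_profile()`.

### The reserve constraint

The Euler update alone can push `MA + MF` past `M0`. The constraint
`M0 - MA - MF >= 0` is enforced after every step: `MF` keeps its own
dynamics, and once the reserve is exhausted fatigue eats into the active
pool (`MA <- M0 - MF`), with both compartments clipped at zero. This
choice — rather than truncating `MF` — is what produces the
characteristic force decline under sustained maximal demand: with the
reserve gone, `MA = M0 - MF` relaxes towards the equilibrium
`M0·R/(F+R)`, the plateau seen in maximal-contraction data. Truncating
`MF` instead would freeze `MA` at the demanded level forever, which
contradicts both the physiology and the benchmark recordings.

### Initial conditions

`simulate_fatigue()` defaults to `MA(0)` equal to the first demand value
(capped at `M0`) and `MF(0) = 0`: standing-start protocols begin at
zero, while a sustained maximal contraction begins at the demanded
level. The calibration and evaluation functions instead initialise `MA`
from the first *measured* energy sample, which is the observable
analogue.

## Numerical scheme

The ODEs are integrated by explicit Euler with `dt = 0.1` s; demand
values given on the 1 s grid are held constant across the ten substeps
of each second (zero-order hold — intent is a step signal, and
interpolation would smear its onsets). All metrics are computed only on
the whole-second evaluation view, matching the 1 Hz measurement grid.

Accuracy is controlled by three closed-form limits used as oracles: the
logistic-type solution of the activation limb (`F = R = 0`, constant
demand), the algebraic decay `MA0/(1 + MA0 βD t)` of the deactivation
limb, and the exponential relaxation of the fatigue equation under
constant activation. At `dt = 0.1` s the integrator matches all three to
better than 0.1 % at `t = 60` s, with the expected first-order
convergence (halving `dt` halves the error; fitted log–log slope 1.00).
The oracle instances are chosen so the fastest time constant spans well
over a hundred steps: the deactivation limb relaxes algebraically, so a
decay that halves within ten steps (e.g. `MA0 = 100`, `βD = 1e-2`)
carries its early truncation error forever and no fixed-step scheme at
this resolution would represent it faithfully. A classical
fine-step Runge–Kutta integration (`simulate_reference()`, `dt = 1e-3`)
provides an independent whole-trajectory check on the sustained-maximal
benchmark, agreeing to ~0.04 % of `M0` pointwise. A stability warning
(class `sprintfatigue_stability`) fires whenever
`dt·MP·αA >= 1` or `dt·MA·βD >= 1`; some published benchmark parameter
sets operate in this regime, so the warning is advisory and computation
proceeds under the non-negativity and reserve clamps.

## Demand construction

Intent is unobservable, so each protocol gets its own rule:

* **Repeated-sprint test** (`sprint_test_demand()`): intervals where the
  1 Hz energy exceeds 40 % of the session maximum for at least 2 s
  (single-second dips bridged) are sprints; the demand is a square wave
  at the *first* sprint's peak energy — the athlete keeps chasing their
  fresh maximum — and zero during recoveries. Detected intervals are
  shifted one bin earlier (`intent_lead = 1`): under zero-order hold the
  demand over second *k* shapes the sample at *k + 1*, so the decision
  to sprint must precede the measured rise. With this lead, a demand
  profile extracted from a model-generated session reproduces the
  generating demand's timing exactly.
* **Match play** (`match_demand()`): the energy series is segmented into
  monotone runs between local extrema (fluctuations under 5 % of the
  session range are ignored as sensor chatter), and the demand
  anticipates each run's destination — the upcoming maximum on rising
  runs, the upcoming minimum on falling runs. The published description
  of this rule conflates the slope and the level of the extremum; this
  implementation reads it as *level at the upcoming extremum*, which is
  the only reading that yields a well-defined step profile in energy
  units. Match demand is built on energy, the model's working unit for
  athletes, not on raw speed.
* **Literature protocols** (`drill_profile()`,
  `gen_literature_protocols()`): square waves from segment
  distance/duration arithmetic (40 m in 10 s = 14.4 km/h), a 60 s
  maximal contraction at 435 force units, and a 15-minute intermittent
  treadmill cycle (walk 6, jog 12, cruise 15, sprint 21 km/h, standing
  recovery). The treadmill cycle places a standing recovery immediately
  after the sprint because that demand drop, issued while the athlete is
  fatigue-saturated, is precisely the condition under which the baseline
  model's derivative-tracking produces negative activation.

## Calibration

`fit_pso()` minimises the time-averaged squared error
$\varepsilon = \frac{1}{T}\int (E_{sim} - E_{meas})^2 dt$, discretised
as the mean squared error over 1 s samples. A `per_minute` normalisation
(summed squared error divided by minutes, i.e. the per-second value
× 60) is available for match-table reporting. Goodness of fit is the
standard `1 - SS_res/SS_tot`; the package defines it explicitly since
reported scores in this literature rarely state the formula.

The optimizer is a global-best particle swarm: 10 particles,
constriction-factor coefficients (inertia 0.7298, cognitive = social
= 1.49618), clamp-to-bound with velocity zeroing on the clamped
coordinate, early stop after 15 iterations without strict improvement.
Swarm size and patience follow the calibration protocol; the remaining
coefficients are the standard constriction defaults and are
configurable. Default bounds are `αA ∈ [1e-5, 1e-3]`,
`βD ∈ [1e-5, 1e-2]`, `F, R ∈ [1e-3, 1e-1]` — appropriate for the
athlete-energy scale; benchmark protocols in other units need their own
bounds, which is why `bounds_spec()` is an argument rather than a
constant. The search is linear in the printed parameter scales by
default (the bounds span at most three decades); `log_scale = TRUE`
searches in log10 space. `M0` is fixed per athlete from mass and maximal
speed, not fitted; `fit_m0 = TRUE` exists for benchmark replication
where the capacity itself was least-squares fitted. `multi_run()`
repeats the fit with seeds derived from one master seed and keeps the
lowest-cost run — ten runs per athlete in the reference protocol — and
everything is bit-reproducible given that seed.

## Synthetic data: what it does and does not establish

`gen_sprint_session()` builds a 10-effort, 300 s stepped demand (5 s
standing lead-in; 15 s effort / 15 s recovery cycles), simulates it with
known parameters, converts the whole-second activation energies back to
speed through the same capacity convention (making the zero-noise round
trip exact by construction), and emits an 18 Hz trace by zero-order hold
with multiplicative Gaussian speed noise (default 2 % — GPS error grows
with speed; an additive option exists). The default generating rates
(`αA = 4e-4`, `βD = 1.2e-3`, `F = 1.5e-2`, `R = 1.9e-2`, all inside the
calibration bounds) and a demand plateau of `0.8·M0` describe an athlete
who attains the demanded level within a few seconds of each effort —
the near-rectangular energy plateaus a repeated-sprint test is designed
to elicit, and the regime in which demand extraction from the measured
trace is self-consistent — while still accumulating enough fatigue that
later efforts fall visibly short. Under these conditions the full
pipeline (generate, smooth, extract demand, calibrate) recovers `F` and
`R` to a few percent at 2 % noise, with the best-run ε at the injected
noise floor.

`gen_match_session()` is a seeded semi-Markov alternating-renewal
process over locomotor states with linear ramps and small
autoregressive jitter. It emulates the intermittent *structure* of
match running for exercising the preprocessing and demand-segmentation
code; it is not a statistical model of real matches, and passing tests
on it demonstrate pipeline correctness, not match realism. Likewise,
synthetic match evaluations use measured series generated by the model
itself under match-like demand, so their near-perfect fit scores verify
plumbing (the calibrated model nests its own generative data), not
field performance. Real wearable data remain the only ground for claims
about real athletes: sensor dropouts longer than the one-second
carry-forward fill, speed-dependent noise structure, and genuinely
unknowable match intent are all outside what the generators emulate.

## Problem sizes and degenerate inputs

The shipped test suite runs the conservation property over 1000
randomized 40 s simulations, the calibration-recovery experiment over
5 noisy sessions × 10 runs (the acceptance script uses 20 sessions), and
the benchmark contrasts at full protocol length; the whole suite
completes in well under a minute on one CPU. Degenerate inputs are
handled explicitly: empty demand profiles, non-finite states and
negative speeds are errors; `closed_form_activation()` refuses
`D >= M0` (coincident roots); `closed_form_fatigue()` returns linear
growth for `R = 0`; constant measured series make `r_squared()` error
rather than return `NaN`; sessions whose energy never exceeds the sprint
threshold raise a protocol-detection error naming the threshold.

## Known limitations

The model has no eccentric-load or central-fatigue terms, one capacity
pool rather than muscle-group surfaces, and inherits the intent
ambiguity of match data: demand extraction is an interpretation, not a
measurement. Rate coefficients are tied to the working unit's numeric
scale, so parameters calibrated in one protocol's units cannot be
transplanted to another without re-fitting. The Euler scheme is
first-order; `dt = 0.1` s is accurate to ~0.1 % against the closed
forms, but users supplying much larger activation rates should heed the
stability warning or reduce `dt`.
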