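# sprintfatigue

Compartmental muscle-fatigue modelling for field sports from wearable
speed data.

Coaches and sport scientists quantify match load with GPS vests sampling
a player's speed at 18 Hz, but aggregate metrics (distance, sprint
counts) say little about *fatigue* — how much of an athlete's capacity
is active, spent, or still available at each moment. `sprintfatigue`
implements a three-compartment motor-unit model of that process,
calibrates it per athlete from a standard repeated-sprint test, and
applies it to match data to produce an interpretable "energy tank" time
series.

## The model

An athlete's total capacity `M0` (J) — by default the peak kinetic
energy, `M0 = ½·m·v²max` — is split at every instant into active (`MA`),
fatigued (`MF`) and available (`MP = M0 − MA − MF`) compartments. The
input is a demanded-activation step profile `MAD(t)`: the level the
athlete is *trying* to reach. With `ΔMAD = MAD − MA`,

    dMA/dt = max(0, ΔMAD) · MP · αA + min(0, ΔMAD) · MA · βD
    dMF/dt = MA · F − MF · R

so activation is fast while reserve units are plentiful, deactivation
scales with the active pool, and capacity shuttles to the fatigued
compartment at rate `F` and recovers at rate `R`. The system is
integrated by explicit Euler at Δt = 0.1 s under the reserve constraint
`M0 − MA − MF ≥ 0`, and all goodness-of-fit metrics are evaluated on
whole-second points only. The four rates `(αA, βD, F, R)` are calibrated
per athlete by particle swarm optimization (swarm 10, early stop after
15 stagnant iterations, best of 10 runs) within physiological bounds,
minimising the time-averaged squared error ε between simulated and
measured kinetic energy.

A baseline variant (`simulate_sns()`), in which the activation rate
equals the demand derivative, is included for contrast: on stepped
demand it produces physically impossible activation rates and negative
activation, which the enhanced model's rate limits eliminate.

## Worked example

Calibrate a synthetic athlete from a generated 10 × 80 m repeated-sprint
session (300 s at 18 Hz, 2 % sensor noise):

```r
library(sprintfatigue)

athlete <- athlete_profile(mass = 80, vmax = 9.14)
athlete
#> <athlete_profile> mass 80.0 kg, vmax 9.14 m/s, M0 3341.6 J (half_mv2)

ses      <- gen_sprint_session(athlete = athlete,
                               noise_sd_fraction = 0.02, seed = 42)
smoothed <- smooth_to_1hz(data.frame(t = ses$raw$timestamp,
                                     speed = ses$raw$speed))
energy   <- speed_to_energy(smoothed, athlete$mass)
demand   <- sprint_test_demand(energy)
demand
#> <demand_profile> 300 s grid, range [0, 2.64e+03] J

fit <- multi_run(demand, energy, athlete$m0, n_runs = 10, seed = 1)
fit
#> <fit_run_set> 10 runs (master seed 1); best run 6
#> <fit_result> run 6 (seed 884616499): epsilon 257.9, R2 1.000, 2010 evaluations
#> <model_parameters> alpha_a 0.00041, beta_d 0.0012, F 0.0148 1/s, R 0.0188 1/s
```

The demand profile is a square wave at the first sprint's peak energy
(2.64 kJ here): the athlete keeps aiming for their fresh maximum even as
later sprints fall short. The best of ten seeded optimization runs
recovers the session's generating rates (F = 0.015 /s, R = 0.019 /s)
almost exactly; ε is the mean squared energy error (J²) on the 1 s grid
and sits at the injected noise floor. `evaluate_on_session()` then
carries these parameters to match data, and `as.data.frame(fit)` gives
the full run table.

A command-line wrapper with the same capabilities is installed at
`system.file("cli", "fatigue.R", package = "sprintfatigue")` with
commands `generate`, `extract-demand`, `simulate`, `fit`, `evaluate`
and `benchmark`.

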