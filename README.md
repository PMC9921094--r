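# mothnav

Closed-loop simulation of odor-source localization by moth-inspired
navigation strategies.

Finding the source of an airborne chemical — a gas leak, explosives, a
disaster survivor — is hard for robots because turbulence breaks the odor
into intermittent filaments with no usable gradient. Insects solve it with
event-driven programs, and the adult male silk moth (*Bombyx mori*) is the
classic template: a stereotyped **surge → zigzag → loop** sequence
re-triggered by every pheromone detection. `mothnav` is for researchers in
bio-inspired robotics and computational neuroethology who want to study such
controllers quantitatively: it provides an intermittent Gaussian-filament
plume with Ornstein–Uhlenbeck wind, bilateral threshold odor sensing with a
four-way body-frame wind class, three navigation policies, the standard
trial protocol, and the evaluation stack (success rates, localization
times, crosswind RMSE, Fisher exact comparisons, behavioral modulation
curves with piecewise-affine gain recovery).

## The controllers

All three share a unicycle agent sampled at 10 ms:

* **RMI** — robust moth-inspired. The surge/zigzag/loop program plus
  multimodal *mode switching*: an odor detection arriving with wind from
  the front selects **active** search, any other wind direction selects
  **inactive** search. Speeds are modulated by the odor-detection frequency
  *f* (onsets per 5 s window) through a piecewise affine law with a
  breakpoint at *f*\* = 0.7 Hz:

  K<sub>v/ω</sub>(f) = a<sub>v/ω</sub> · f + b<sub>v/ω</sub>,

  with separate coefficients per mode × branch (the published table fitted
  to silk-moth behavior; e.g. active, f ≤ 0.7: K_v = 53.6 f + 129 mm/s;
  inactive: K_v = 105 mm/s at every f), clamped to the robot's speed range
  v ∈ [50, 250] mm/s, |ω| ∈ [0.5, 3] rad/s.
* **SZL** — the same program at constant 150 mm/s / 1.5 rad/s, wind
  ignored.
* **SC** — surge–cast: surge upwind on detection, cast crosswind with
  doubling legs after 1 s without contact (150 mm/s / 1.5 rad/s).

A trial succeeds when the agent enters a 0.1 m radius around the source,
and fails on leaving the field or after 3 min.

## Worked example

```r
library(mothnav)

# the velocity law, evaluated before clamping
velocity_gain(c(0, 0.4, 0.8), "active", gain_table(), clamp = FALSE)
#> $K_v
#> [1] 129.00 150.44 154.80
#> $K_w
#> [1] 1.8200 2.1752 1.5380
```

At f = 0 the active-mode translational gain is the intercept b_v = 129 mm/s;
at 0.4 Hz the low-frequency branch gives 53.6·0.4 + 129 = 150.44 mm/s; at
0.8 Hz the high-frequency branch takes over and speed falls again — the
moth slows down when plume contact is very frequent, i.e. near the source.

```r
# one trial in the crossed-cue arena: fan beside the source blows +y while
# the plume drifts toward the start pose
tr <- run_trial(scenario_preset("b"), "rmi", seed = 7)
tr
#> <plume_trial> RMI, scenario b, seed 7: success in 14.12 s
#>   (1412 ticks, crosswind RMSE 0.211 m)
plot(tr)   # trajectory, source circle, start point

# a batch, summarised the way the robot protocol is scored
summarize_batch(run_batch(scenario_preset("b"), "rmi",
                          n_trials = 5, base_seed = 1))
#> <batch_summary> RMI, scenario b: 3/5 successes (60%)
#>   localization time  median 14.4 s (range 14.3-15.4)
#>   crosswind RMSE     median 0.214 m (mean 0.402)
```

The localization time is the simulated time to enter the success radius;
the crosswind RMSE, `sqrt(mean((y_i - y_odor)^2))` over the whole
trajectory, measures meandering across the plume axis — small values mean
the agent moved smoothly inside the plume. `compare_success_counts()`
(Fisher exact) and `compare_rank_sum()` compare two batches;
`modulation_curves()` + `fit_piecewise_gains()` re-derive the gain law from
logged behavior.

A command-line front end ships in `inst/cli/mothnav`
(`simulate / evaluate / analyze / fixtures` subcommands over YAML configs
and CSV logs); shipped arena configs are under `inst/extdata/`. The methods
vignette (`vignettes/mothnav-methods.Rmd`) documents the plume and wind
models, every tunable parameter with units and defaults, the calibration of
the sensing defaults, and what the simulator does and does not reproduce.

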