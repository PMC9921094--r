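---
title: "Moth-inspired odor source localization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moth-inspired odor source localization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothnav)
```

## The problem

A walking agent must find the source of an airborne odor. Odor does not form
a smooth gradient: turbulent advection breaks it into intermittent filaments,
so gradient descent is useless and animals instead use event-driven
strategies — surging on contact, casting crosswind after losing it. The adult
male silk moth is the classic model organism: its female-localization program
is a stereotyped surge / zigzag / loop sequence re-triggered by each
pheromone detection.

`mothnav` implements three such controllers inside a closed-loop 2-D
simulator:

* **RMI** (robust moth-inspired): the surge/zigzag/loop program plus two
  *search modes* selected by multimodal agreement — when an odor detection
  arrives with wind from the front, the agent searches *actively*, scaling
  its speeds with the odor-detection frequency; when odor arrives with wind
  from any other direction it searches *inactively*, at a low constant
  speed. Speeds follow the piecewise affine law
  `K_{v,omega}(f) = a_{v,omega} f + b_{v,omega}` with a breakpoint at
  0.7 Hz, using the published coefficient table fitted to silk-moth
  behavior.
* **SZL** (surge–zigzag–loop): the same program at constant speeds
  (150 mm/s, 1.5 rad/s), ignoring wind entirely.
* **SC** (surge–cast): the flying-insect strategy — surge *upwind* on
  detection, cast crosswind with growing legs after losing the plume
  (150 mm/s, 1.5 rad/s).

## The environment model

The plume is a set of Gaussian filaments released from the source at
10 s⁻¹, advected by the wind, jittered diffusively
(SD 0.02 m·√dt per step), and growing at 0.005 m/s from an initial spread of
0.02 m. Concentration at a point is the kernel sum
`Σ q exp(-r²/2σ²)/σ²`. The wind is spatially uniform at each instant and
follows an exact-discretisation Ornstein–Uhlenbeck process in direction and
speed around the scenario mean (1.0 m/s), so the configured turbulence SDs
are the stationary SDs for any timestep.

Three preset arenas mirror the standard robot protocol (odor source at the
origin, 0.1 m success radius, 3 min limit, failure on leaving the
2.5 m × 2 m field):

| scenario | fan | agent-sensed wind | plume transport | turbulence (dir SD) |
|---|---|---|---|---|
| a | (-0.5, 0) | +x | same wind | 0.1 rad |
| b | (0, -0.3) | +y | steady drift toward the start pose | 0.3 rad |
| c | (-0.5, 0) | +x | same wind | 0.5 rad (gusty, speed SD 0.3) |

**Scenario b and the two flows.** A fan placed beside the source and blowing
across it cannot itself carry odor to an agent starting 1.5 m down-field; in
a real room the odor reaches the agent through slow ambient drift while the
agent's local anemometry is dominated by the fan jet. Scenario b therefore
decouples the two: filaments are advected by a steady transport flow along
`atan2(0.3, 1.5)` (so the displaced centerline passes through the start
pose), while the sensed wind fluctuates around +y. This reproduces the
defining feature of the crossed-cue arena — wind direction is a misleading
proxy for odor direction — which is exactly what degrades the wind-led SC
strategy. In scenarios a and c a single flow plays both roles.

The simulation steps at dt = 0.01 s (the robot's 10 ms sensor sampling) and
the plume is spun up for 6 s before each trial so the arena holds an
established plume at t = 0.

## Sensing

Two point sensors sit 0.05 m ahead of the body center, ±0.03 m laterally; a
detection is concentration above a threshold. The wind is rotated into the
body frame and classified into four quadrant classes (front / back / left /
right, ±45°, axial classes winning ties, previous class held below a
0.05 m/s dead-band).

Detections enter the controllers through two channels:

* **level** — either sensor above threshold this tick; this is what
  (re)triggers surge and selects the search mode;
* **onsets** — false→true edges, counted per sensor with a refractory
  period; a 5 s sliding window of onsets divided by 5 s is the
  odor-detection frequency f (resolution 0.2 Hz) that drives the gain law.

**Calibrating threshold and refractory.** The gain table is defined on the
frequency range observed in the tethered-moth experiments, roughly
0–1.4 Hz. Under the default plume, a stationary probe calibration gave
threshold = 100 and refractory = 0.5 s (physically, the odor sensor's
recovery time): in-plume onset frequencies then span ~0.5–1.4 Hz, falling
toward zero with distance and crosswind offset. With a much shorter
refractory the same plume yields 2–4 Hz — outside the law's fitted domain,
where the extrapolated active-mode law falls below the inactive constant and
inverts the speed contrast the algorithm is built on. Both parameters are
configurable.

## The controllers in detail

The published coefficient table is stored in `gain_table()`. Its printed
active-mode f > 0.7 row (a_v = −114, a_ω = 246, b_v = −1.59, b_ω = 2.81)
yields negative speeds and a 246 rad/s angular gain under the stated column
order; the default `corrected = TRUE` swaps the two middle entries, which
restores positive speeds and near-continuity of K_v at the breakpoint
(166.52 vs 166.2 mm/s). The raw printed reading stays available behind
`corrected = FALSE`. Evaluated gains are clamped to v ∈ [50, 250] mm/s and
|ω| ∈ [0.5, 3] rad/s — the robot's practical speed range; the source
describes such clamps without printing values.

```{r}
gain_table()
```

Geometry the source leaves open, fixed here once:

* surge steering: a fresh onset turns the agent 30° toward the detecting
  sensor (both sensors at once = frontal, no turn), then straight;
* zigzag: first turn 60° toward the last detection side, then reversals of
  120° so the heading alternates symmetrically (+60°, −60°, +60°) about the
  last surge axis — the classical casting fan; a single-amplitude
  alternation would scan one side only;
* each zigzag leg runs straight for 1.0 s; the loop rotates with the sign
  of the third turn;
* the moth-like controllers start in zigzag (scanning), SC starts casting;
* SC: 1.0 s lost-plume timeout; cast legs 1.5 s doubling per reversal,
  capped at 8 s so the cast corridor stays bounded; legs are aligned
  perpendicular to the wind using the wind bearing (the four-way class alone
  is 90° wide, too coarse to align a leg); U-turn arcs alternate the side
  they bulge toward so they cancel instead of ratcheting the corridor
  sideways.

Surge persisting under continuous contact follows from the re-triggering
rule: every detection tick resets the surge timer, so the program only falls
back to zigzag 0.5 s after contact is lost. Mode is re-evaluated at
detection ticks and retained between them.

## Metrics and analysis

`summarize_batch()` reports the success rate, localization times
(successful trials only — failures have no defined time) and the per-trial
crosswind RMSE `sqrt(mean((y_i - y_odor)^2))`, the standard measure of
meandering across the plume axis. Success counts are compared with a
two-sided Fisher exact test (`compare_success_counts()`); continuous metrics
with a Wilcoxon rank-sum hook (`compare_rank_sum()`). The multiple-group
rank procedure named in the original protocol is intentionally not
implemented; distributions and the pairwise hook are reported instead.

`modulation_curves()` re-derives the behavioral law from logs: per-tick
samples are split by mode and 0.1 Hz frequency bin and summarised by
medians (bins without samples are reported empty, not zero).
`fit_piecewise_gains()` then fits `K = a f + b` per branch around the fixed
0.7 Hz breakpoint by least squares. Fed a noiseless log generated by the
law itself, it returns the generating coefficients to numerical precision —
the analysis closes the loop on the controller.

```{r}
f <- rep(seq(0.05, 1.45, 0.1), each = 20)
g <- velocity_gain(f, "active", gain_table(), clamp = FALSE)
log <- data.frame(f = f, mode = "active", v_cmd = g$K_v, w_cmd = g$K_w)
fit_piecewise_gains(modulation_curves(log), breakpoint = 0.7)
```

## What the simulator does and does not show

A 100-trial-per-algorithm comparison in scenario b (run by the package's
acceptance tests) reproduces the qualitative findings of the robot
experiments: the modulated controller stays inside the plume (smallest
crosswind RMSE) and finds the source far more often than the wind-led SC
strategy, which surges toward the fan and away from the odor. In scenario a,
where wind and odor cues agree, SC is strong — as wind-led strategies are in
wind-tunnel-like conditions.

Limitations to keep in mind when reading those numbers:

* The default plume is a narrow ribbon (σ ≈ 3 cm at 1.5 m downwind) —
  far thinner relative to the agent than a real room-scale ethanol plume.
  The odor-driven moth program has no anemotactic heading anchor, so once
  the heading random-walks off the plume axis the terminal loop can park
  the agent; absolute success rates of RMI/SZL are therefore lower than the
  physical-robot ones, and in the gusty scenario c the plume snakes too
  fast for the moth program to hold station at all.
* Wind sensing is noiseless up to the quadrant quantization; real
  anemometers on a moving robot are much worse, which is an additional
  reason SC underperforms physically.
* Sensor lag, recovery chemistry and active odor intake are not modeled;
  detection is instantaneous thresholding.

Passing tests therefore certify the controller mathematics, the protocol,
the estimators and the qualitative orderings under this generator — not
quantitative agreement with any physical trajectory.

## Numerical choices

* Exact OU discretisation (`a = exp(-dt/tau)`, innovation SD
  `sd·sqrt(1-a²)`) keeps the stationary law timestep-independent.
* Filament release is deterministic (`floor(rate·t)` after t seconds), so
  plume mass is seed-independent.
* Turn progress integrates commanded angular speed in angle
  (`turn_remaining -= ω dt`), so turn geometry is invariant to the gain in
  force at the time.
* Headings are wrapped to (−π, π]; a bearing exactly on a ±45° class
  boundary goes to the axial class.
* Trials are seeded per trial (`base_seed + i - 1`); identical seeds give
  bit-identical trajectories, logs and outcomes.
* All external units are the robot's (mm/s, rad/s, m, s, Hz); internal
  integration converts mm/s to m/s once at the kinematics step.
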