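---
title: "Methods: region statistics, angle-ratio laws and the movement model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region statistics, angle-ratio laws and the movement model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubeswarm)
```

## The problem

Schooling fish forced through a narrowing channel reorganise: they bunch
into the central band of the channel and move through it faster than along
the tapering walls. `tubeswarm` provides the three layers needed to study
this quantitatively: (i) geometric partition of the channel and per-frame
region statistics from tracked trajectory tables, (ii) regression of the
middle-over-edge speed and count ratios on the cosine of the channel's
opening angle, and (iii) an agent-based movement model that generates the
same statistics from local interaction rules.

## Channel geometry and region partition

A tube is a trapezoid in pixel coordinates whose parallel sides — the wide
entrance and the narrow exit opening — are perpendicular to the x-axis; the
x-axis points in the direction fish exit. Wall angles `theta_l` and
`theta_r` are signed angles of each wall's direction against the x-axis, and
the *included angle* is `theta = |theta_r - theta_l|`, restricted to
[0, 90). The *middle region* is the rectangle obtained by sweeping the exit
opening back along the tube; the two residual triangles are the edge
regions. These three polygons tile the trapezoid exactly (the tests assert
area conservation to a 1e-9 relative tolerance, plus agreement of the
classifier with an independent winding-number point-in-polygon oracle).

Two conventions are deliberate:

* **Boundary ties go to the middle region.** Classification must be
  deterministic; any point exactly on a middle/edge boundary is labelled
  `middle`.
* **Fixtures are symmetric.** The study never published wall coordinates,
  only each tube's included angle, and the angle is the only geometric
  quantity entering either law. Fixtures are therefore built symmetric about
  the tube axis with a 200 px exit opening and 400 px length — scales
  consistent with a 2592x1944 px overhead video. `included_angle_from_walls()`
  exposes the raw-segment computation, which is invariant under rigid
  rotation/translation of the coordinates.

## Trajectory tables and anomaly handling

Tracked tables carry, per fish per frame: position (px), `speed_x` stored as
a magnitude, `speed_y` signed, and the combined speed
`sqrt(speed_x^2 + speed_y^2)` (px/frame). Tracker output contains occasional
glitches — the shipped frame-37 table has one row whose components
(641, 525 px/frame) are physically impossible and inconsistent with its
recorded combined speed of 0. `flag_anomalies()` flags a row when the
recomputed combined speed differs from the recorded one by more than 0.01
after 2-decimal rounding, or when a component exceeds a configurable
`max_speed` (default 100 px/frame, an order of magnitude above the fastest
plausible row). Flagged rows are excluded from region averages, never
repaired: the intended correction is unknowable. CSV serialization rounds to
2 decimals — the tables' native precision — so a write/read round trip is
lossless at that precision.

## Region statistics and the averaging convention

Per frame, `V_middle`/`V_edge` are mean combined speeds and
`N_middle`/`N_edge` counts over the fish classified into each region (the
two edge triangles pooled). Ratios use the **zero convention**: when a
denominator (edge mean speed, or edge count) is 0, the ratio is defined as
0. This follows the printed per-frame tables, which show `Ratio-s = 0.00`
for frames with `V_edge = 0.00`.

Per-tube summaries are the **mean of per-frame ratios**, not the ratio of
mean speeds. The distinction is decisive: over tube A's schooling window
(frames 28, 37, 46) the mean of ratios gives 1.42 while the ratio of means
gives 1.34, and only the former reproduces the published summary row. The
frame window itself is an analyst's judgement of when the swarm is actually
schooling; it is an explicit input (`frames =`) rather than a hidden rule,
defaulting to all frames. Only tube A's window is recoverable from the
published material, which is also why the shipped summary table has six
rows.

## The angle-ratio laws

With one summary row per tube, the two laws are

* `ratio_s = slope * cos(theta) + intercept`, fitted by ordinary least
  squares; the reported `corr` is the Pearson correlation of the inputs.
* `ratio_n = exp(alpha * cos(theta) - beta)`, fitted as a log-linear OLS of
  `ln(ratio_n)` on `cos(theta)`. The log-linear route is deterministic and
  matches the model's functional form; rows with a zero count ratio cannot
  enter the log and are excluded and reported.

The published coefficients (1.5033/0.1545 and 3.5971/2.0173) were fitted on
all eight tubes, but only six summary rows were ever printed; fitting those
six gives 1.444/0.206 and 2.636/1.196. The package therefore treats the
published coefficients as *reference values* for prediction
(`predict_speed_ratio()`, `predict_number_ratio()`) and validates the
fitting code by exact recovery on synthetic summaries generated from those
laws (to 1e-9 noiseless; within 0.1 under log-normal/Gaussian noise of
sd 0.05 at n = 50). The MSE of the count-ratio fit is reported on a
configurable scale (linear-ratio by default, log-ratio optionally) since
either is defensible for a multiplicative model.

The predictors accept theta in [0, 90] — the closed-form laws are defined at
90 even though a physical tube's included angle stays below it.

## The movement model

Each fish updates synchronously in discrete frames:

```
v_i(t+1) = v0 + v_s,i(t) + v_n,i(t) + v_w,i(t)
p_i(t+1) = p_i(t) + v_i(t+1) * dt
```

| parameter | meaning | default | rationale |
|---|---|---|---|
| `v0` | forward drive, px/frame | 3 | Table-2 speed scale (most rows 5–12 px/frame once interaction terms add in) |
| `k` | neighbour gain, 1/frame | 0.1 | keeps interaction velocities bounded at the observed speed scale |
| `b` | wall gain, 1/frame | 0.8 | study value |
| `d1`, `d2` | repulsion/attraction thresholds, px | 10, 30 | about one and three body lengths at the video's pixel scale |
| `d3` | wall-avoidance range, px | 18 | study value |
| `fov_half_angle` | visual sector half-angle, deg | 90 | the 180° field of view commonly assumed for fish |
| `fov_range` | visual range, px | 200 | the exit-opening scale; beyond it fish are visually irrelevant |
| `n_fish` | swarm size | 30 | study simulation size |

Choices where the model statement left room:

* **Zone order.** The constraint `d1 < d2` fixes the reading: repulsion
  below `d1`, attraction above `d2`, parallel between. (A prose reading with
  attraction immediately above `d1` contradicts that constraint.)
* **Empty field of view** gives `v_s = v_n = 0`. The source model did not
  consider the case (fish were always close together); zero is the only
  choice that leaves a straggler with pure forward drive rather than
  undefined behaviour.
* **Wall term as stated.** The push has magnitude `b * d_w` — *growing*
  with wall distance up to the `d3` cutoff, which is the opposite of a
  classical repulsive potential. It is implemented exactly as stated; the
  consequence is that the push vanishes at the wall itself, so the velocity
  rule alone cannot guarantee containment.
* **Collision resolution.** Because of the above, the simulation loop
  detects wall collisions and projects any position that would cross a wall
  (or back out of the entrance) to the interior, which is the
  collision-avoidance behaviour the simulation procedure describes. Fish
  crossing the *exit* line are marked passed and removed from the dynamics.
* **Ties.** The nearest-fish tie breaks to the lowest id; the nearer-wall
  tie to the left wall. Both are arbitrary but deterministic.
* **Initialisation** places fish uniformly inside the tube with region
  quotas from the count-ratio law (`round(n r / (1+r))` in the middle, the
  rest split between the edge triangles) and speeds scaled so the
  middle/edge ratio matches the speed-ratio law with overall mean `v0`,
  headings jittered within 15° of the exit direction. All randomness flows
  through R's RNG under a single seed, so runs are bit-reproducible.

## Kernel density occupancy curves

`kde_1d()` is a Gaussian-kernel density estimate on a regular 512-point grid
spanning the data plus three bandwidths each side, bandwidth by Silverman's
rule (`bw.nrd0`). The curve is renormalised to unit *trapezoidal* integral
over its grid: truncating a Gaussian at three bandwidths leaves ~0.3% of
mass outside, and the curve is used as a probability density over the tube,
so exact unit mass on the reported grid is the more useful contract. Tests
cross-check the shape against `stats::density()` at the same bandwidth and
against the closed-form normal density at n = 1e4. Degenerate input (all
positions identical) falls back to a fixed 1 px bandwidth.

## The synthetic generator

`generate_frames()` emulates the *statistical* structure of tracked tables:
exact per-frame region counts (the middle gets `round(n r/(1+r))` fish for
target ratio `r` — n = 16 and r = 3 give the observed 12/4 split), uniform
placement within each region, speeds from a truncated normal (nonnegative)
whose region means are in the target speed ratio, and headings jittered
around the exit direction. It does **not** emulate temporal autocorrelation
of real trajectories, tracker identity swaps, fish body extent (points, not
ellipses), or out-of-tube fish. Passing tests on synthetic data therefore
validates the arithmetic of the pipeline and the recoverability of
prescribed region structure — not the biological realism of any particular
recording. `generate_summary_dataset()` plays the same role one level up,
drawing per-tube summary rows directly from the two laws with controllable
noise for fit-recovery tests.

## Problem sizes and runtime

The test suite and acceptance script run at deliberately modest sizes: 16 or
30 fish, simulations of 300–1000 steps (a 30-fish swarm clears the default
tube in about 60), 1e4-point classification and field-of-view oracle sweeps,
1e5-point Monte-Carlo area checks, and 50-point noisy-fit recoveries. These
sizes put every stochastic check at least three standard errors from its
threshold while keeping the whole suite under a couple of minutes on one
CPU.

## Known limitations

* Only trapezoids with entrance and exit perpendicular to the x-axis are
  representable; curved or skewed channels are out of scope.
* The movement model is two-dimensional and ignores hydrodynamic coupling
  (fin wakes), body size, and inter-individual variability.
* The per-tube frame windows other than tube A's are not recoverable from
  the published material; analyses of the other tubes must choose their own
  windows.
* The wall-avoidance magnitude as stated weakens near the wall; containment
  is provided by the explicit collision-resolution step, not by the
  velocity field itself.
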