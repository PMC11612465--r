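# tubeswarm

Analysis and simulation of collective fish traffic through tapering
(trapezoidal) tube channels.

When a schooling fish swarm swims through a narrowing channel, the swarm does
not spread evenly: it concentrates in the central band of the channel and
moves faster there. `tubeswarm` quantifies that behaviour from tracked
per-frame trajectory tables and reproduces it with a simple agent-based
movement model. It is aimed at behavioural ecologists and swarm-robotics
researchers working with overhead-video tracking of confined collective
motion.

## The model

**Region partition.** The channel is a trapezoid whose parallel sides (the
wide entrance and the narrow exit opening) are perpendicular to the x-axis,
the x-axis pointing toward the exit. The *middle region* is the rectangle
spanned by the exit opening swept along the tube; the two residual triangles
are the *left-edge* and *right-edge regions*. The tube's *included angle* is
θ = |θ_r − θ_l|, the opening angle between the two walls.

**Region statistics.** For each video frame, V_middle and V_edge are the
mean combined speeds of the fish in the two regions and N_middle / N_edge
their counts; Ratio-s = V_middle / V_edge and Ratio-n = N_middle / N_edge
(defined as 0 when the denominator is 0). Per-tube summaries average the
per-frame ratios over a frame window in which the swarm is schooling.

**Angle–ratio laws.** Across tubes the summary ratios follow

    Ratio-s = 1.5033 · cos θ + 0.1545            (linear, Pearson r = 0.98)
    Ratio-n = exp(3.5971 · cos θ − 2.0173)       (exponential in cos θ)

fitted by ordinary least squares (the count law on the log scale).

**Movement model.** Fish i updates its velocity synchronously:

    v_i(t+1) = v0 + v_s,i(t) + v_n,i(t) + v_w,i(t)

where `v0` is a constant forward drive along the exit direction; `v_s` is
`0.5 k (p_c − p_i)`, an attraction toward the centroid `p_c` of fish ahead
of i inside its visual sector (half-angle 90°, radius `fov_range`); `v_n`
acts on the nearest visible fish — repulsion `−k (p_n − p_i)` closer than
`d1`, attraction `+k (p_n − p_i)` beyond `d2`, nothing in the parallel band
between; and `v_w` is a wall-avoidance push of magnitude `b·d_w` along the
inward normal of the nearer wall whenever the wall distance `d_w ≤ d3`
(defaults `b = 0.8`, `d3 = 18` px, 30 fish).

## Worked example

```r
library(tubeswarm)

## tube A: symmetric trapezoid with a 29.05-degree included angle
geom <- tube_fixture("A")
geom
#> <tube_geometry> A
#>   walls: theta_l = -14.525 deg, theta_r = 14.525 deg
#>   included angle: 29.05 deg (cosine 0.87)
#>   length: 400.0 px, entrance width 407.3 px, exit width 200.0 px

## summarize the per-frame region statistics over the schooling window
summarize_tube(study_table("tubeA_stats"), geom, frames = c(28, 37, 46))
#>   tube_id mean_ratio_s mean_ratio_n angle_deg    cosine n_frames
#> 1       A     1.423333     2.466667     29.05 0.8741963        3

## speed-ratio / cos(angle) correlation across the six summarized tubes
tab <- study_table("summaries")
round(pearson_corr(tab$cosine, tab$mean_ratio_s), 2)
#> [1] 0.98
fit_linear_law(tab$cosine, tab$mean_ratio_s)
#> <linear_law> ratio_s = 1.4441 * cos(theta) + 0.2057  (r = 0.98, n = 6)

## simulate swarm traffic through a 25-degree tube
sim <- simulate_swarm(model_params(), make_tube_fixture(25),
                      n_steps = 300, seed = 1)
sim
#> <swarm_simulation> 30 fish, 60 frames, 30 passed the exit (seed 1)
occupancy_fraction(sim$frames, make_tube_fixture(25))
#> [1] 0.969
```

The tube-A summary says fish in the middle region moved on average 1.42
times faster than fish in the edge regions and were 2.47 times more
numerous. In the simulation, 97% of fish-frames fall in the middle region —
well above its 69% share of the tube's area — showing the model reproduces
the observed central concentration.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/tubeswarm.R report
Rscript inst/scripts/tubeswarm.R validate frames.csv
Rscript inst/scripts/tubeswarm.R simulate --config sim.yaml --seed 1 --out frames.csv
```

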