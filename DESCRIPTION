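Package: tubeswarm
Title: Collective Motion of Fish Swarms in Trapezoidal Tubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of collective fish movement through tapering (trapezoidal)
    tube channels: partitions the channel into middle and edge regions, computes
    per-frame region statistics (mean speed and occupancy ratios) from tracked
    trajectory tables, fits the linear speed-ratio and exponential count-ratio
    laws against the cosine of the tube's included angle, estimates kernel
    density occupancy curves, and simulates swarm traffic with a zonal
    repulsion/parallel/attraction movement model including wall avoidance.
    Ships a synthetic trajectory generator so the full pipeline is testable
    without video tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
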