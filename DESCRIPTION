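Package: glycoflow
Type: Package
Title: Coarse-Grained Simulation and Analysis of Flow over a Wall-Tethered Glycocalyx Brush
Version: 1.0.0
Authors@R: person("Glycoflow", "Developers", email = "glycoflow@example.org",
    role = c("aut", "cre"))
Description: A desk-scale coarse-grained nonequilibrium particle simulator for
    body-forced solvent flowing over wall-anchored stiff oligomer cores bearing
    flexible tethered sugar chains, confined between a frozen lower wall and a
    frozen ceiling, together with the trajectory post-processing stack used to
    characterise such flows: region-partitioned velocity profiles and temporal
    contours, planar velocity fields with streamline integration and vorticity,
    forward-difference shear-stress statistics with two-sample
    Kolmogorov-Smirnov comparisons and ratio-exceedance reports, and
    polar-coordinate tracking of tethered-chain segments (swing, swirling,
    uncoiling, motion correlation). Trajectories are exchanged as extended-XYZ
    text files with a plain-text topology sidecar, so externally produced
    particle trajectories can be analysed through the same interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
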