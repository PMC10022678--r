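Package: sptfield
Title: Multistate Lateral Diffusion Analysis and Mosaic Membrane Field
    Simulation for Single-Particle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of 2-D single-molecule trajectories of membrane
    proteins: mean-square-displacement (MSD) estimation of diffusion
    coefficients and localization error, displacement-distribution
    Rayleigh-mixture fitting with AIC selection of the number of diffusion
    states, hidden Markov model segmentation of trajectories into mobility
    states with per-state diffusion coefficients, occupancies and
    exponential state lifetimes, bootstrap confidence intervals, and
    membrane-viscosity estimation under the Saffman-Delbruck and
    Stokes-Einstein-like hydrodynamic models. Includes a Monte-Carlo
    simulator of diffusion on a mosaic membrane made of fast and slow
    microdomains embedded in a middle-viscosity background, which doubles
    as the package's synthetic-data generator, plus a pure hidden-Markov
    trajectory generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
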