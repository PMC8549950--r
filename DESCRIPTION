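Package: xbridge
Title: Two-State Crossbridge Models of Cardiac Active Force Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-filament crossbridge kinetics for cardiac muscle in the
    Huxley (1957) two-state tradition. Provides the classic attachment and
    detachment rate laws and their analytic steady state, a finite-volume
    solver for the generalized transport-reaction equation with permissivity
    and velocity-dependent crossbridge destruction, the exact two-moment
    ordinary differential equation reduction with closed-form constant-velocity
    solutions and fast length-step asymptotics, closed-form calibration of the
    four or five model parameters from macroscopic measurements (isometric
    tension, attached fraction, maximum shortening velocity, inverse
    force-velocity sensitivity, and fast-step stiffness), virtual experiment
    protocols (force-velocity sweeps, quick-release length steps, Hill 1938
    utilities), a seeded synthetic-measurement generator with a matching
    parameter-recovery estimator, and a Boltzmann-quadrature engine reducing
    soft-spin power-stroke energy landscapes to effective two-state rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
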