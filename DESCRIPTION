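Package: idioloc
Title: Idiothetic Localization by Particle Filtering in Bounded Arenas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates an agent that localizes inside a familiar 2D arena
    using only error-prone self-motion estimates (path integration) fused
    with a remembered boundary map, via sequential Monte Carlo (particle
    filtering) with boundary-crossing culling. Provides arena geometry with
    rotational-asymmetry analysis, rodent-plausible motion error models
    (Wiener heading drift, fractional step-length noise), place-stability
    and circular-variance localization metrics, stochastic grid-cell spike
    simulation with rate-map, gridness and spatial-information analysis,
    retrospective (reverse-replay and lineage-based) inference of past
    poses, and config-driven experiment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
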