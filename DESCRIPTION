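Package: plexisim
Title: Dermal Transport Simulation with a Subpapillary Plexus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates drug transport in the viable skin after topical
    application, coupling three-dimensional diffusion in the papillary
    dermis to one-dimensional blood advection along capillary-loop
    centerlines and to two well-stirred compartments representing the
    venular and arteriolar layers of the subpapillary plexus. Provides
    steady-state and transient solvers on a periodic structured grid,
    sensitivity sweeps over plexus size, plexus depth, blood velocity and
    vessel density, response-surface regression utilities, closed-form
    depthwise comparison models, a brute-force verification oracle with
    manufactured-solution convergence checks, and a command-line entry
    point for running configured simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
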