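Package: stenoflow
Title: Transient Axisymmetric Finite-Volume Simulation of Biomagnetic
    Blood Flow in Stenosed Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates pulsatile, shear-thinning (Carreau) blood flow with
    heat transfer through an axisymmetric stenosed artery under a transverse
    magnetic field. A collocated finite-volume discretization with SIMPLE
    pressure-velocity coupling solves the coupled mass, momentum and energy
    equations, including magnetohydrodynamic damping, Joule heating, viscous
    dissipation and a magnetization body-force hook. Ships closed-form
    pipe-flow oracles (Poiseuille and the Bessel-form Hartmann profile) for
    validation, grid-convergence tooling, and post-processing for wall shear
    stress, flow resistance and recirculation detection, plus scenario
    configuration files, presets and VTK/CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
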