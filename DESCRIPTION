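Package: coreshell
Title: Dissolution-Diffusion-Binding Models of Drug Release from
    Core-Shell Microparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Continuum simulation of drug release from a microparticle
    consisting of a drug-loaded core enveloped by a thin polymeric shell,
    such as a layer-by-layer (LbL) polyelectrolyte coating homogenized
    into a single equivalent layer.  The model couples nonlinear
    (Noyes-Whitney-type) dissolution of solid drug in the core,
    Fickian diffusion of the dissolved phase through core and shell with
    flux continuity at the interface, irreversible first-order binding of
    drug within the shell, and a perfect-sink outer boundary.  Provides a
    radially symmetric finite-volume solver, a 2D P1 finite-element solver
    on triangulated disk and ellipse cross-sections for shape-sensitivity
    studies, cumulative-release metrics including the release time,
    least-squares calibration of model parameters against observed release
    curves, one-at-a-time parameter sweeps, a synthetic release-data
    generator, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
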