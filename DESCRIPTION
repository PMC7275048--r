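Package: introntoggle
Title: Active-Site Geometry, Path Collective Variables and Splicing
    Kinetics for Group II Intron Toggling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for the conformational toggling of
    the group II intron active site between the two steps of splicing.
    Computes named geometric descriptors (triple-helix distances, nucleobase
    plane angles, ion contacts) on PDB structures and trajectories, classifies
    triple-helix versus disrupted states and detects potassium-release events;
    builds discretized reference paths between conformers and evaluates the
    path collective variables S and Z; parses adaptive-width metadynamics hill
    logs and reconstructs free-energy surfaces with basin and minimax-barrier
    reports, including a toy biased Langevin sampler for validation; fits
    sequential first-order splicing kinetics (precursor -> intermediate ->
    excised intron) and interconverts rate constants and activation free
    energies through the Eyring-Polanyi equation. Ships seed-deterministic
    synthetic-data generators so every analysis is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
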