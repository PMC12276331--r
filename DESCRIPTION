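Package: bondkin
Title: Single-Molecule Force Spectroscopy and AFM Particle Volumetrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for dynamic force spectroscopy (DFS) of
    receptor-ligand bonds and for volumetric oligomer analysis of AFM
    height images. Implements the Bell-Evans model of slip-bond rupture,
    the Williams Markov model for load-sharing parallel bonds, rupture
    event detection in force-distance retract traces, heteroscedastic
    Gaussian-sum probability densities of rupture forces and particle
    volumes, loading-rate segmentation, pseudo-first-order binding
    kinetics with effective-concentration conversion to bimolecular
    on-rates, and mixture-based assignment of oligomeric states from
    particle volumes. A Monte-Carlo force-curve simulator (worm-like-chain
    tether, Bell kinetics, mono/bivalent binding over contact time) and a
    synthetic AFM image generator provide ground-truth data for
    validating every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
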