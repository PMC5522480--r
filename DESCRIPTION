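Package: helicoil
Title: Helix-Coil Transition Analysis and Contrast-Variation SANS Modelling for Side-Chain-Switchable Polypeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for cationic polypeptides whose
    secondary structure is switched by protonation of side-chain 1,2,3-triazoles
    (binary to unitary hydrogen-bonding pattern). Provides topology and formal
    charge bookkeeping for model polypeptides, helix-geometry fitting (radius,
    twist, rise, RMSD to an ideal alpha-helix), geometric hydrogen-bond
    detection with backbone/water/side-chain partitioning, backbone
    centre-of-mass to water radial distribution functions with block-averaged
    errors and depletion-zone detection, a small-angle neutron scattering
    forward model (orientationally averaged cylinder form factor, Percus-Yevick
    and rescaled-MSA charged-sphere structure factors), simultaneous
    multi-contrast fitting, and a contrast-variation estimator of the water
    volume fraction inside the scattering particle. A synthetic-data generator
    supplies conformations, solvated frames, folding trajectories, noisy
    multi-contrast SANS curves and titration tables with the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    minpack.lm,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
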