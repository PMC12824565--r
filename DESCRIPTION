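Package: fretspt
Title: Single-Molecule FRET and Single-Particle Tracking of Membrane Receptor Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Combined single-molecule FRET (smFRET) and single-particle
    tracking (SPT) analysis of ligand-induced receptor dimers imaged by
    two-channel TIRF microscopy. Provides a ground-truthed synthetic movie
    generator emulating sparse membrane receptors with monomer-dimer
    interconversion, sub-pixel Gaussian spot localization with fiducial-based
    channel registration, trajectory linking with gap closing, FRET trace
    vetting by anti-correlation and single-step photobleaching, correction
    of FRET efficiencies for spectral crosstalk and detection imbalance,
    segmentation of trajectories into FRET-active and donor-only parts,
    mean-squared-displacement diffusion estimation with confined/free motion
    classification, jump-angle statistics, and exponential dimer-lifetime
    fitting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
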