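Package: tpcresonance
Title: Modal Analysis and Tap-Test Spectroscopy of Ear-Bone Structures
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the resonance of multi-component elastic
    structures such as the cetacean tympanoperiotic complex. Provides a
    multi-material tetrahedral finite-element modal solver with fixed-base
    constraints, material sweeps, uniform scaling and component ablation; an
    impact (tap) excitation spectral pipeline with coherent multi-tap
    averaging, peak picking and per-location amplitude maps; a mode-matching
    stage that scores spatial agreement between measured amplitude maps and
    simulated surface-normal displacement; and synthetic-data generators
    (parametric labeled meshes and modal-superposition tap recordings) with
    full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RSpectra,
    jsonlite,
    yaml,
    rhdf5,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
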