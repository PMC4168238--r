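Package: egopull
Title: Simulated Force Spectroscopy of Pyranose Oligomers by Enforced
    Geometry Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-molecule stretching experiments on
    alpha-D-galacturonic acid oligomers by Enforced Geometry Optimization
    (EGO): geometry minimization on an energy surface modified by a
    constant external force pair applied to two anchor atoms.  Provides a
    molecular structure model with XYZ/PDB readers and writers, a built-in
    molecular-mechanics energy model whose six-membered rings exhibit
    chair, twist-boat and inverted-chair basins, a quasi-Newton EGO engine
    with rupture detection and vibrational stability analysis,
    Cremer-Pople ring puckering coordinates with canonical conformer
    classification, a stretch-relax force-ladder protocol with adaptive
    minimal-transition-force search, force-extension curve and
    optimization-history analysis, and a synthetic builder for pyranose
    rings, galacturonic monomers and (1->4)-linked oligomers at arbitrary
    ring pucker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
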