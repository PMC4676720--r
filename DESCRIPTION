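Package: shieldfit
Title: Electrostatic Charge Shielding of PIP2 by Cations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative model of electrostatic charge shielding of
    phosphatidylinositol 4,5-bisphosphate (PIP2) by divalent and polyvalent
    cations and its effect on phospholipase C (PLC) activity. Provides a
    multi-metal/multi-ligand chelator speciation solver with pH, ionic
    strength and temperature corrections for computing free-ion assay
    conditions; a Boltzmann counterion-accumulation model of free PIP2 and
    normalized PLC activity; staged nonlinear least-squares estimation of
    the shielding parameters (L, K, Y, W) with bootstrap uncertainty and
    IC50 extraction; a synthetic-data generator for dose-response curves and
    Michaelis-Menten fluorogenic progress curves; and standard-curve based
    rate extraction for fluorogenic enzyme assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
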