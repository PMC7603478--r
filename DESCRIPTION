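Package: woundsim
Title: Hybrid Agent-Based and Finite-Element Simulation of Post-Burn Skin Contraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-stochastic, hybrid cell-based/finite-element model of
    dermal wound contraction. Discrete macrophage, fibroblast and
    myofibroblast agents are coupled to finite-element fields for the
    signalling molecules PDGF, TGF-beta and tPA on a deforming
    triangulated domain, with Kelvin-Voigt viscoelastic tissue mechanics
    driven by temporary cell-boundary forces and plastic element-edge
    forces, and symmetric orientation tensors for fibrin and collagen.
    Cellular division, differentiation and apoptosis follow exponential
    clocks whose rates depend on the local TGF-beta concentration and
    contact strain energy density. A Monte Carlo layer samples patient
    variability distributions and summarises contraction statistics,
    including a two-parameter Weibull fit of reversed day-4 wound areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
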