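Package: pertraction
Title: Mass-Transfer Modelling for Membrane-Assisted Solvent Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modelling toolkit for membrane-assisted (pertractive) liquid-liquid
    extraction of hydrophobic solutes in hollow-fibre membrane contactors.
    Estimates solute diffusivities (Wilke-Chang with Le Bas molar volumes),
    individual film coefficients (Leveque tube-side, parallel-flow shell-side,
    porous-membrane), and overall aqueous-basis mass-transfer coefficients via
    the resistance-in-series model for both contactor operation modes. Includes
    the non-steady-state recirculating two-reservoir extraction model, its
    linearised form for fitting module extraction efficiency and overall mass
    transfer from concentration time series (with seeded bootstrap
    uncertainty), partition-coefficient estimation from two-phase equilibrium
    replicates, solvent screening and ranking from partition/property tables,
    and a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
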