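Package: chemosel
Title: Chemoselectivity Prediction for Organocatalytic Carbonyl Chemistry
    from Conceptual-DFT Reactivity Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale tools for rationalizing and predicting the
    chemoselectivity of N-heterocyclic carbene (NHC) catalyzed
    functionalizations of carbonyl compounds.  Computes global conceptual-DFT
    reactivity indices (chemical potential, hardness, electrophilicity omega,
    nucleophilicity N against the tetracyanoethylene reference) from
    frontier-orbital energies, local Parr functions from vertical radical-ion
    spin populations, a calibrated linear free-energy relationship mapping the
    omega + N index sum of a nucleophile/electrophile pair to the barrier of
    the chemoselective step, Boltzmann/Eyring conversions between free-energy
    differences and enantiomeric excess, product ratios or rate constants, and
    an energetic-span style ranking of competing multi-step free-energy
    profiles by kinetics and thermodynamics.  A Hueckel molecular-orbital
    solver generates synthetic orbital-energy and spin-population inputs for
    testing; no electronic-structure calculations are performed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
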