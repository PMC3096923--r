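Package: mixscreen
Title: Relative Ligand Affinities from Competitive Binding of Mixtures and
    Chromatographic Peak Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates relative association constants (K_X/K_A) of candidate
    ligands in mixtures from competitive binding to a target immobilized on
    magnetic particles, followed by magnetic recovery of target-ligand
    complexes, solvent extraction, concentration, and quantification of each
    ligand by liquid chromatography-mass spectrometry in selected-ion
    monitoring mode. Implements the mass-action equilibrium solver for
    multi-ligand competitive binding to a single class of sites, the linear
    peak-area response model with its quantification prerequisites, the
    binding-ratio and relative-affinity estimators (with and without the
    ligand-depletion correction), assay-design planners for the minimum
    target quantity (parameter-dependent and experimental approaches) and for
    mixture composition ratios (stepwise and exponential escalation), and a
    forward simulator of the whole assay for validation against sealed
    synthetic truths emulating the biotin-derivative/streptavidin model
    system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
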