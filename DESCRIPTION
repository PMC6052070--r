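Package: frondosim
Title: Membrane Biophysics of Saponin-Sterol Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling how membrane sterol structure modulates the
    action of amphiphilic saponins. Implements an implicit-bilayer insertion
    scan (logistic hydration function with hydrophobic and lipid-perturbation
    restraints), coarse pairwise docking of interface-oriented molecules with
    van der Waals, electrostatic and hydrophobic energy terms, a lattice
    Monte Carlo monolayer simulation driven by pairwise interaction matrices
    with sterol-domain quantification and Welch comparison, and the
    accompanying wet-lab arithmetic for calcein-leakage assays and isothermal
    titration calorimetry (blank subtraction, binding-isotherm fitting,
    thermodynamic identities). Ships seeded synthetic generators for fixture
    molecules, interaction-matrix scenarios, titration series and
    fluorescence traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    png,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
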