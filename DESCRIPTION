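Package: peptherm
Title: Thermodynamic Screening of Peptide Leaders for Bi-Substrate Kinase Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the thermodynamic screening workflow used to select a
    peptide leader for a bi-substrate protein kinase inhibitor, with human CK2
    alpha as the model target. Implements combinatorial positional peptide
    library enumeration with monoisotopic and average mass calculation,
    isobaric-class grouping and mass-spectrometric peak assignment for
    pull-down enrichment scoring; global bi-exponential fitting of
    relaxation-filtered NMR decays and affinity ranking by the fast
    transverse relaxation rate; single-site binding isotherm fits for
    nanoDSF and microscale thermophoresis titrations with Kd to free-energy
    conversion and error propagation; one-site isothermal titration
    calorimetry simulation and fitting with perfusion-cell displacement
    bookkeeping; four-parameter logistic IC50 dose-response fitting with
    fold-enhancement comparison; and a ternary-complex cross-dependency test
    for independence of peptide and ATP-site ligand binding. Seeded synthetic
    data generators emulate each assay design so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
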