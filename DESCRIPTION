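Package: aqpflux
Title: Aquaglyceroporin Selectivity, Permeability Kinetics and Molecular
    Evolution Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the functional diversification of
    aquaglyceroporin (Aqp10) paralogs. Estimates osmotic water and solute
    permeabilities from Xenopus oocyte swelling kinetics, extracts and
    classifies the aromatic/arginine (ar/R) selectivity filter from protein
    alignments, computes Nei-Gojobori dN/dS between sequence groups with
    codon-bootstrap standard errors, reconstructs marginal maximum-likelihood
    ancestral sequences under Tamura-Nei, dates gene-duplication nodes with a
    single-calibration relative-rate clock, and ships simulators (ODE-based
    oocyte swelling, Gillespie codon evolution) so that every estimator can be
    validated against known ground truth. Includes in-silico PCR, restriction
    digestion and dot-plot utilities for paralog-discriminating assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    multcomp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
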