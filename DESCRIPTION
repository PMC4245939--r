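Package: nucleoprop
Title: Nucleobase Interaction Propensity Scales and mRNA-Protein Profile Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for amino-acid/nucleobase interaction
    studies in crowded aqueous mixtures. Computes radial distribution functions and
    Kirkwood-Buff integrals from particle frames and evaluates the microscopic
    stability criterion for nucleobase/water mixtures; derives amino-acid and
    sidechain-analog interaction propensity scales from solute-nucleobase and
    solute-water interaction-energy traces (with water-count rescaling to a common
    mole fraction) and relative base-vs-base preference scales; builds window-averaged
    nucleobase-content profiles of mRNA coding sequences and propensity profiles of
    their cognate proteins, and scores their complementarity by per-pair Pearson
    correlation with a uniform random-scale permutation null for proteome medians.
    Includes deterministic synthetic-data generators (mixture configurations with
    known pair structure, energy traces with known means, cognate mRNA/protein
    proteomes with a tunable composition-propensity coupling) so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'mixture.R'
    'scales.R'
    'profiles.R'
    'significance.R'
    'synthetic.R'
    'io.R'
    'nucleoprop-package.R'
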