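Package: BIRquant
Title: Quantitative Analysis of Break-Induced Replication Assays in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for yeast double-strand-break repair
    assays built around the AM1003 disomic chromosome III system:
    classification of colony marker phenotypes into repair classes,
    decomposition of Ade+ Leu- outcomes into break-induced replication
    (BIR), gross chromosomal rearrangements (GCR) and the invisible
    half-crossover class (HC-II), a chromatid-segregation model
    justifying the HC-II imputation, reversion-rate estimation for
    BIR-associated frameshift mutagenesis, Poisson quantification of
    droplet digital PCR copy-number kinetics with Boltzmann sigmoidal
    fits, ChIP-qPCR enrichment ratios, tetrad and random-spore
    suppression analysis, and a monopartite nuclear localization signal
    (NLS) consensus scanner. Seeded synthetic-data generators emulate
    every assay so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'nls-scan.R'
    'repair-outcomes.R'
    'segregation.R'
    'mutagenesis.R'
    'amber.R'
    'chip.R'
    'spores.R'
    'synth-data.R'
    'io-tables.R'
    'fixtures.R'
    'BIRquant-package.R'
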