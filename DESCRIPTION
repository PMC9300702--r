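Package: baitquant
Title: Quantitative AP-MS Interactome Scoring and Endothelial Trafficking Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free quantitative scoring of affinity-purification mass
    spectrometry (AP-MS) pull-downs against an unlabeled control: replicate
    validity filtering, log2 scaling, downshifted-normal imputation of
    left-censored missing values, paired control ratios, one-sample t tests
    with Benjamini-Hochberg q values, fold-change/p-value interactor calling,
    and contaminant-repository background flagging. Includes membrane-topology
    and subcellular-location classification of called interactors,
    hypergeometric category enrichment, and estimators for three functional
    readouts of receptor trafficking at endothelial junctions: FRAP
    mobile-fraction recovery, surface-biotinylation capture-ELISA
    internalization, and transwell tracer permeability. A synthetic-data
    module generates intensity matrices with intensity-dependent dropout,
    FRAP recovery traces, and paired assay readouts so the whole pipeline is
    testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
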