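Package: microcast
Title: Imputation of Nucleosome-Resolution Chromatin Contact Maps from
    Epigenomic Tracks and Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Imputes nucleosome-resolution (200-bp) chromatin contact maps
    from lower-resolution Hi-C and a small panel of epigenomic signal
    tracks using a hybrid 1D-convolutional / graph-convolutional network
    with a contact-profile head and a loop head whose outputs are summed.
    Includes integrated-gradients attribution of predicted contacts to
    input features, loop and stripe calling at 1-kb resolution with
    pile-up aggregation, a full evaluation suite (stratum-adjusted
    correlation coefficient, distance-stratified Pearson, fragment-level
    Spearman with conservation/compartment/replication-timing
    stratification, A/B compartment calling, eQTL-TSS pile-ups), and a
    seeded synthetic-data generator with planted loops, stripes and
    compartments that serves as the test substrate for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    withr,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core_data.R'
    'preprocess.R'
    'model.R'
    'attribution.R'
    'structures.R'
    'evaluation.R'
    'synthetic.R'
    'config.R'
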