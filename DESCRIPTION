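Package: bartkit
Title: Design, Simulation and Analysis of Barcode-Assembled Targeted
    Sequencing Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted amplicon sequencing with combinatorial
    dual DNA barcoding. Implements design of mutually dissimilar barcode
    and adapter panels and of multiplexed primer sets by simulated
    annealing with a nearest-neighbor duplex-energy model; a plate-aware
    paired-end read simulator with ground truth; demultiplexing of
    dual-indexed amplicon reads into per-amplicon count matrices with
    single-mismatch barcode correction; spike-in based normalization with
    empty-well and doublet filtering; and ratio-based genotype calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
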