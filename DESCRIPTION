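Package: divscan
Title: Genomic Divergence Scans for Hybrid-Zone Population Pairs
Version: 0.1.0
Authors@R: person("Divscan", "Maintainers", email = "divscan@example.org",
    role = c("aut", "cre"))
Description: Per-site relative (Weir-Cockerham theta-hat / FST) and absolute
    (dxy) divergence from multi-sample diploid genotypes in VCF, with the
    filtering, ratio-of-sums combining, sliding-window scans, bootstrap
    genomic baselines and recombination-distance decay analysis used in
    genome scans of the Heliconius erato speciation continuum, plus a
    Balding-Nichols synthetic hybrid-zone generator so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
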