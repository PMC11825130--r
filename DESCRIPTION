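Package: sweepshare
Title: Selective Sweep Scans, Sweep Sharing Tests, and Asymptotic
    McDonald-Kreitman Estimation Across Populations
Version: 0.1.0
Authors@R: person("Packaged", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and comparing selective sweeps across
    multiple resequenced populations. Implements a composite windowed sweep
    statistic (diversity-deficit, extreme-frequency, and flanking-linkage
    sub-statistics), cubic-spline smoothing with coalescent-simulation
    outlier thresholds and gap merging to call sweep regions, replicate-based
    accuracy estimation, accuracy-adjusted hypergeometric tests of sweep
    sharing with Benjamini-Yekutieli correction, and hierarchical asymptotic
    McDonald-Kreitman estimation of the adaptive fixation proportion from
    0-fold/4-fold site classes. A coalescent synthetic-data generator with a
    known sweep truth table makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
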