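Package: acceptorvar
Title: Splicing-Effect Prediction for Intronic Variants Near 3' Splice Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Featurizes single-nucleotide variants at intronic positions Int-50
    to Int-3 upstream of splice acceptor sites of internal coding exons
    (acceptor-site strength, branch-point and polypyrimidine-tract signals,
    AG-dinucleotide creation, RNA-binding-protein motif changes), trains a
    gradient-boosted decision-tree classifier to separate splicing-pathogenic
    from common variants, evaluates it with the seven guideline measures of
    binary-classifier performance plus ROC and precision-recall curves, and
    exposes a coordinate-level prediction interface. Includes a synthetic
    genome/annotation/variant simulator with planted acceptor-site biology so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
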