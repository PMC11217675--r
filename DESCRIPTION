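Package: ucnescan
Title: Dinucleotide-Arrangement Features for Identifying Ultraconserved
    Non-Coding Elements
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies ultraconserved non-coding element (UCNE) like DNA
    sequences from dinucleotide arrangement alone. Implements nine
    composition features (GpC frequency, CC+GG frequency, spacing-distance
    pattern ratios, GC/AT-rich triplets, enriched dinucleotide pairs,
    alternating-dinucleotide ratio, GC content), length-matched genomic
    control sampling with soft-mask awareness, exact dinucleotide-preserving
    shuffles, radial SVM / random forest / neural network classification
    with full evaluation reports, and a Monte-Carlo test of ClinVar variant
    representation inside UCNE intervals. A first-order Markov sequence
    simulator with tunable GC content and dinucleotide enrichment generates
    labelled benchmarks so the whole pipeline runs without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    e1071,
    randomForest,
    nnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
biocViews: Sequencing, Classification, FeatureExtraction, MachineLearning
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
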