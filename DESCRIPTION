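Package: circlass
Title: Sequence-Feature Classification of Plant Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies plant circular RNAs (circRNAs) against a long
    noncoding RNA (lncRNA) background from sequence alone. Extracts three
    feature families from candidate transcripts: overlapping k-mer
    frequencies (k = 1..4 plus GC content, 341 features), optimal open
    reading frame length and coverage, and a positionwise integer encoding
    of the +/-50 bp genomic windows around the two splice sites of the
    back-splice junction. Trains and evaluates random-forest (and
    comparison) classifiers with stratified repeated ten-fold
    cross-validation, reports recall, precision, accuracy, F1, Matthews
    correlation and ROC/PR curves, and ships a seeded synthetic fixture
    generator with tunable planted signal so the whole pipeline is testable
    without external downloads. Includes redundancy removal at a percent
    identity threshold and Tukey box-whisker length outlier filtering for
    dataset preparation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    digest,
    dplyr,
    e1071,
    generics,
    ggplot2,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
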