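Package: splicevar
Title: Mechanistic Scoring and Classification of Sequence Variation at
    RNA-Processing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores splice-site strength under trainable positional
    second-order Markov log-odds models and position weight matrices,
    classifies genomic variants in splice-site windows into five effect
    classes (disrupting, weakening, neutral, enhancing, activating) with
    threshold calibration against an independent PWM scheme, and rescues
    novel RNA-processing elements from population-scale RNA-seq evidence:
    putative cleavage sites from poly-A-tailed reads with ranked hexamer
    signal scanning, putative novel introns from split-read junctions, and
    ADAR-consistent A-to-G RNA-editing candidates with intron-retention
    association tests.  Ships deterministic synthetic-fixture generators
    (genome, annotation, variants, reads) with planted ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    GenomicRanges,
    optparse,
    jsonlite
Config/testthat/edition: 3
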