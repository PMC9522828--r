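Package: cfalpha
Title: Read-Level Methylation Marker Discovery and Stacked Ensemble
    Classification for Cell-Free DNA
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale implementation of a liquid-biopsy methylome
    analysis pipeline. Marker unit regions are defined by in-silico MspI
    digestion of a reference sequence; cancer-specific and tissue-specific
    hyper- and hypomethylation markers are discovered from the read-level
    alpha-value (the fraction of methylated CpGs in one sequencing read)
    with automatic threshold learning, pair-support scoring and
    reference-plasma filtration; plasma samples are summarised into four
    deconvolved feature profiles of normalised log read counts; and a
    two-level stacked ensemble (per-view linear support vector machines
    stacked into a random forest) detects cancer and predicts its tissue
    of origin.  A beta-binomial synthetic-methylome generator produces
    paired tumour/normal tissues and plasma read mixtures with planted
    differentially methylated regions so the whole pipeline is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    e1071,
    randomForest,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
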