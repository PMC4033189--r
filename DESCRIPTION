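Package: nascentr
Title: Nascent Transcription Analysis for GRO-seq: Quantification,
    Differential Calling, Pausing and Enhancer RNA Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for strand-specific nascent-transcription (GRO-seq)
    data: gene-level quantification over promoter and gene-body windows,
    fpkm normalization, negative-binomial exact-test differential
    transcription calling with median-of-ratios size factors and a fitted
    mean-dispersion trend, RNA polymerase II pausing and promoter-divergence
    indices, enhancer-RNA detection at consensus transcription-factor
    binding sites against a uniform Poisson background, distance-based site
    categorization, gene-set overlap statistics, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    stats,
    utils,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
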