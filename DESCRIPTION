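Package: riptarget
Title: Target Calling for RIP-seq with 3'-End PolyA-Site Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the mRNA targets of an RNA-binding protein from
    RIP-seq experiments quantified by 3'-end (QuantSeq-style) sequencing.
    Provides UMI deduplication and strand-aware assignment of read 3' ends
    to polyadenylation-site windows, median-of-ratios size factors with a
    manual scaling of immunoprecipitation libraries, a negative-binomial
    generalized linear model with a replicate-matched design and Wald
    contrasts, a two-stage enrichment filter (IP versus IgG control, then
    IP versus input) that defines targets at 1.5-fold enrichment and
    adjusted p <= 0.05, and downstream comparisons of binding efficiency,
    ribosomal engagement and qPCR delta-delta-Ct validation. A synthetic
    data generator with planted ground truth supports calibration and
    recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    DESeq2
Config/testthat/edition: 3
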