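Package: loopGWAS
Title: Mapping Fine-Mapped GWAS Variants to Effector Genes via Chromatin Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates chromatin loop calls from multiple loop-calling
    algorithms and resolutions, performs CTCF-based anchor quality control,
    classifies candidate cis-regulatory elements (enhancers and promoters) as
    active from ATAC-seq open chromatin and replicate-thresholded histone-mark
    ChIP-seq evidence, chains fine-mapped GWAS credible-set variants through
    enhancer-promoter (and enhancer-enhancer-promoter) loops to candidate
    effector genes, joins molecular QTL annotations, and tests for a shared
    causal variant between GWAS and molecular QTL signals with approximate
    Bayes factor colocalisation. Includes a seeded synthetic-data generator
    that produces a complete miniature input bundle with planted ground truth
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
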