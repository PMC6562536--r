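Package: CREconserve
Title: Annotation and Cross-Species Conservation of Liver Cis-Regulatory
    Elements
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates cis-regulatory elements (promoters, active promoters,
    enhancers, broad H3K4me3 domains and super-enhancers) from histone
    ChIP-seq peak calls, and classifies their cross-species conservation as
    un-conserved, sequence-only conserved or functionally conserved using
    chain-based coordinate mapping with minimum-match semantics. Includes
    ROSE-style enhancer stitching with a geometric elbow cutoff, chromatin
    state overlay of sequence-only conserved elements, expression linkage
    with quantile normalization and differential-expression threshold
    filtering, core transcriptional regulatory circuitry construction from
    position-weight-matrix scans of super-enhancer constituents, and a
    seeded synthetic-data generator that plants conservation fractions,
    super-enhancer signal geometry and expression effects so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: ChIPSeq, Epigenetics, FunctionalGenomics, Annotation,
    Coverage, PeakDetection, Software
RoxygenNote: 7.3.3
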