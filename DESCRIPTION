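Package: hepcre
Title: Hepatocyte Subtype Consolidation and Cis-Regulatory Element
    Annotation from Single-Cell Multi-Omics Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of single-cell multi-omics summaries from
    normal and hypertensive liver tissue: consolidation of annotated
    hepatocyte clusters into subtypes by Jaccard similarity of their top
    upregulated genes, selection of condition marker genes by intersection
    with pathway gene sets, peak-category composition statistics on
    accessible-chromatin peaks, classification of peaks into promoters and
    enhancers from histone ChIP-seq evidence (H3K4me3; H3K4me1 plus
    H3K27ac), hypergeometric motif enrichment, and construction of
    evidence-filtered gene-regulatory networks. Includes a fully seeded
    synthetic-data generator that plants ground truth for every stage, and
    a deterministic end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
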