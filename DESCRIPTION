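Package: gscrna
Title: Circular and Long Noncoding RNA Profiling in Germline Stem Cells
Version: 0.1.0
Authors@R:
    person("GSC", "Transcriptomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for profiling noncoding RNAs in male (SSC)
    versus female (FGSC) mouse germline stem cell RNA-seq designs: backsplice
    junction calling for circular RNAs with GT/AG splice-site refinement, a
    six-step long noncoding RNA identification cascade with positional
    classification, FPKM quantification and negative-binomial sex-biased
    differential expression, autosome/X odds-ratio enrichment with Fisher's
    exact test, coding-noncoding co-expression networks, and competing
    endogenous RNA (ceRNA) networks based on shared miRNA seed sites. Includes
    a fully deterministic synthetic-data generator that plants backsplice
    junctions, sex-biased fold changes, co-expressed pairs, and ceRNA triples
    with ground truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
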