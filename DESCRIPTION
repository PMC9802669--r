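Package: methexpr
Title: Methylome-Transcriptome Comparative Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative epigenomics of bisulfite
    methylomes and RNA-seq transcriptomes in a two-genotype, two-stage
    design: binomial-test methylcytosine calling with CG/CHG/CHH context
    classification, sliding-window Fisher-exact detection of differentially
    methylated regions (DMRs) with interdependent-region merging, FPKM
    differential expression and K-means/PCA profile clustering, topological
    overlap co-expression neighbour selection, and DMR-DEG integration
    statistics (association by gene body plus 2 kb upstream, hypergeometric
    enrichment, hyper/hypo by up/down cross-tabulation, windowed
    methylation-expression correlation). A synthetic-data module generates
    genomes, methylomes, and count matrices with known planted DMRs, DEGs,
    and methylation-expression anti-correlation so that every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
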