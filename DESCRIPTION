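Package: coexminer
Title: Signed Gene Co-Expression Networks with Module Mining, Motif
    Scanning and Functional Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds signed weighted gene co-expression networks from
    RNA-seq count data and mines them for biology: count filtering and
    TMM/RPKM normalisation, fold-change differential expression calls,
    soft-threshold selection against a scale-free topology criterion,
    topological overlap, average-linkage module detection with eigengene
    merging, MCODE dense-subgraph decomposition, degree-percentile hub
    identification, hypergeometric term enrichment with
    Benjamini-Hochberg correction, and position-weight-matrix scanning
    of promoter regions with exact score p-values. A synthetic-data
    generator produces count matrices, genomes and annotation tables
    with planted modules, differential expression, enriched terms and
    motif instances, so that every stage of the pipeline can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    igraph,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
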