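Package: lgtnet
Title: Alignment-Free Inference of Lateral Genetic Transfer Networks and
    Genetic Exchange Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lateral genetic transfer (LGT) between groups of
    microbial genomes with an alignment-free TF-IDF scoring of shared
    k-mers, calls lateral segments with gap merging, maps them onto
    annotated genes, consolidates the calls into directed group-to-group
    LGT networks, enumerates maximal cliques of the undirected network as
    genetic exchange communities, identifies core nodes stable across a
    grid of word lengths k, and tests Gene Ontology term enrichment among
    lateral genes with Fisher's exact test under FDR control. Includes a
    synthetic-genome simulator with planted transfers for benchmarking
    precision and recall of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    stringi,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
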