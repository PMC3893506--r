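Package: tempomir
Title: Integrative Time-Course Analysis of mRNA and microRNA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating time-course mRNA and microRNA microarray
    expression profiles. Implements probe filtering, quantile normalization
    and log-ratio computation; selection of temporally changed features and
    assignment to model temporal profiles with permutation significance;
    identification of microRNA targets as predicted pairs with significantly
    negative expression correlation under a permutation-based false discovery
    rate; pathway enrichment (Fisher's exact test with Benjamini-Hochberg
    adjustment) and a pathway activity statistic with a random-gene-set
    permutation null; core-gene selection on merged directed pathway graphs
    by relative betweenness centrality; and promoter scanning with position
    weight matrices followed by Jaccard similarity clustering of binding-site
    content. Ships a synthetic-data generator with planted ground truth so
    the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    limma,
    igraph,
    jsonlite,
    fgsea,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
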