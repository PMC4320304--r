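Package: orthoclock
Title: Reciprocal-Best-Hit Orthology and Phylogenetics for Plant Clock Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for tracing gene families across plant genomes the way
    comparative studies of the circadian clock do it: deterministic
    protein-space database search with E-value ranking, iterative
    cross-species reciprocal-best-hit classification of orthologues and
    paralogues with gene-family expansion, splice-site-aware (GT..AG)
    re-annotation of exon-intron gene models against transcript or homologue
    evidence, codon-preserving back-translated multiple alignment,
    neighbour-joining trees on pooled composite-likelihood (TN93) distances
    with bootstrap support and outgroup rooting, and a birth-death simulator
    of gene families with known orthology truth for end-to-end validation.
    Ships a curated catalogue of barley homologues of Arabidopsis clock genes
    and a pipeline driver that runs the whole inference chain on synthetic or
    user data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
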