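Package: ecotypeR
Title: Comparative Genomics of Closely Related Bacterial Genomes
Version: 0.1.0
Authors@R: person("Lake", "Workbench", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delineating bacterial ecotypes from pairs and panels of
    closely related genomes. Implements reciprocal-best-hit average amino acid
    identity (AAI), single-copy ortholog selection with concatenated
    phylogenomics (progressive alignment, neighbor joining, bootstrap),
    algorithmic genomic-island and recombination hot-spot detection from
    synteny breaks, GC deviation and tRNA/recombinase integration signatures,
    a metabolic-module inventory from feature annotations, taxonomic-rank
    zoning from 16S identity crossed with AAI, and a genome-pair simulator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    data.table,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
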