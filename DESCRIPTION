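Package: virocycle
Title: Iterative De Bruijn Graph Assembly and Gene-Cassette Discovery for
    Viral Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles mixed viral communities from short paired-end reads by
    iterating de Bruijn graph assemblies over a ladder of kmer values,
    preferring kmers that close circular contigs (complete circular viral
    genomes), subtracting read pairs recruited by the retained contigs, and
    repeating until no reads map or no contigs of at least 1 kb remain.
    Downstream tools discover conserved gene cassettes without reference
    databases: ORFs are called on contigs, clustered into protein-coding
    families by global-alignment identity, families are merged into cassettes
    by shared-contig overlap, and gene co-orientation is scored against the
    25 percent chance level. A bipartite contig-to-reference-protein network
    can be built from external homology hit tables and exported for Cytoscape.
    A seeded simulator of synthetic viral communities (circular and linear
    genomes, skewed abundances, sequencing error, spike-in mixtures) provides
    a reproducible testbed, including a genome-recovery benchmark for
    low-abundance spike-ins.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
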