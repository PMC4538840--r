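Package: ganiclust
Title: Genome-Wide Average Nucleotide Identity, Alignment Fraction and
    Species-Level Genome Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Computes pairwise genome-wide average nucleotide identity (gANI)
    and alignment fraction (AF) between prokaryotic genomes from their
    protein-coding gene sequences, using bidirectional best hits derived
    from a k-mer seeded local aligner with a 70% identity / 70% coverage
    retention filter.  Genomes are clustered into species-level cliques and
    clique-groups by Bron-Kerbosch maximal clique enumeration on the graph
    whose edges require minimum pairwise AF >= 0.6 and minimum pairwise
    gANI >= 96.5.  Existing species labels can be audited against the
    clusters (single/multiple x homogeneous/heterogeneous categories,
    assignment proposals for unclassified genomes, type-strain conflicts),
    and an empirical intra-species probability model over binned (AF, gANI)
    can be fitted and queried.  A deterministic synthetic genome-evolution
    simulator (substitutions, gene loss, indels, draft-style truncation)
    generates test collections with planted species structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
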