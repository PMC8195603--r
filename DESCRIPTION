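Package: contextscan
Title: Contextual Comparative Genomics of Gene Neighborhoods and Domain Architectures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects conserved gene neighborhoods across prokaryotic genomes
    using nucleotide-distance, directionality and phylum-spread filters;
    clusters proteins by a length-coverage/score-density single-linkage
    contract; builds domain-architecture adjacency and profile-search
    retrieval networks; and provides the statistics used in contextual
    analysis of biological conflict systems: positional-bias chi-squared
    tests under a slot-availability null, column-wise Shannon entropy with
    a mean-entropy diversification test, hypergeometric enrichment for
    binary taxon traits such as multicellularity, the per-organism
    polydomain score, and Z-score-based average-linkage (UPGMA) trees.
    Includes a seeded synthetic-genome generator that plants conserved
    cassettes, positional biases and lineage-specific expansions with
    recorded ground truth, so every pipeline stage can be benchmarked
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
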