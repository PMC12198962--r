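Package: orthoscout
Title: Feature Architecture-Aware Targeted Ortholog Search and Phylogenetic
    Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profile-based targeted ortholog search seeded from a single
    protein sequence. Iteratively compiles a taxonomically diverse core
    ortholog group under a combined alignment-score / feature-architecture
    similarity criterion, trains a profile hidden Markov model, and searches
    orthologs across arbitrary taxon collections with a reciprocity
    criterion. Every ortholog is scored for bidirectional feature
    architecture similarity (FAS). Downstream utilities assemble, filter,
    binarize and embed the resulting feature-aware phylogenetic profiles,
    select paralog representatives, and flag putative contaminations and
    horizontal gene transfers from similarity-search hit tables and contig
    maps. A synthetic-scenario generator produces taxonomies, proteomes,
    annotations and ground-truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
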