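Package: amplicross
Title: Cross-Platform 16S rRNA Amplicon Classification, Bias Auditing and
    Phylogenetic Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to compare full-length (nanopore-style) and short
    V3-V4 (Illumina-style) 16S rRNA amplicon sequencing of the same
    bacterial community. Provides a synthetic-community generator with
    nine designated hypervariable regions and configurable platform error
    models, degenerate-primer in-silico PCR and amplicon extraction,
    semi-global best-hit read classification with an identity gate,
    greedy 97% identity clustering with closed-reference assignment, an
    error-free "recreated dataset" bias audit of the short-read target
    region, cross-platform OTU table merging with per-rank Spearman
    concordance, and phylogenetic beta diversity (generalized UniFrac,
    principal coordinates analysis, permutational MANOVA) together with
    inverse Simpson rarefaction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
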