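Package: ghprospect
Title: Targeted Gene-Family Prospecting in Unannotated Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects members of a protein family (such as GH45 cellulases) in
    unannotated genome assemblies, screens candidate genes for microbial
    contamination by margin-based last-common-ancestor taxonomic assignment,
    profiles presence/absence of the family across a species set, and
    characterises the family's evolutionary history (independent origins,
    Dollo gain/loss histories, duplication/loss reconciliation, tanglegrams)
    by comparing gene trees with species trees. A synthetic-data module
    simulates species trees, gene-family histories with duplication, loss and
    horizontal transfer, diverged protein sequences planted as single-exon
    genes in contigs, contaminant contigs, and homology-hit tables with
    taxonomically decaying bit scores, so that every stage of the pipeline is
    verifiable against a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phytools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
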