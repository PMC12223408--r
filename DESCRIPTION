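Package: foramMetabar
Title: Curation and Phylogenetic Community Analysis for Freshwater
    Foraminifera Metabarcoding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for 18S rRNA amplicon metabarcoding surveys of freshwater
    foraminifera and other rare protist lineages. Implements a simplified
    swarm-style OTU caller (dereplication, single-linkage clustering at edit
    distance 1, singleton/chimera/divergence filters), a deterministic and
    fully audited OTU-table curation cascade (read floors, occurrence filters,
    flagged-contaminant removal to fixpoint, seeded rarefaction without
    replacement, two-rule index-switching correction, final abundance filter),
    and phylogeny-aware community analysis (weighted UniFrac from branch
    enumeration, principal coordinates analysis, relative-abundance
    classification, habitat-occupancy summaries). A synthetic-community
    generator with ground-truth ledgers makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    phangorn,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phyloseq,
    igraph,
    jsonlite,
    optparse
biocViews: Metagenomics, Microbiome, Phylogenetics, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
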