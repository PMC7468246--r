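Package: coralbaits
Title: Hybrid-Capture Bait Design and Post-Capture Curation for Coral
    Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing 120 bp target-enrichment baits from
    clustered ortholog alignments of stony corals (Scleractinia) and for
    curating post-capture sequence data into a partitioned phylogenomic
    supermatrix.  Provides a seeded Smith-Waterman local-alignment engine
    used by all homology screens, orthogroup representation and
    contamination filters, codon-aware back-translation, exon-aware
    iterative bait-window tiling, symbiont cross-hybridization and
    self-hybridization screening, DNA-barcode sample verification with
    coverage-ratio contamination calls, gene-tree-based paralog and
    contaminant pruning, supermatrix construction with
    parsimony-informative-site statistics, and a deterministic synthetic
    data generator with a planted-anomaly truth ledger for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
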