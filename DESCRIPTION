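Package: tryptome
Title: Curation and Evolutionary Analysis of Trypsin-Domain Protein Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assemble and analyse the trypsin-domain complement of a
    proteome (the "tryptome"). Post-processes profile-HMM per-domain tables
    (HMMER3 domtblout) into curated domain architectures with partial-hit
    merging, E-value gating and pairwise overlap resolution; summarises
    trypsin-associated domain abundance and cross-taxon architecture sharing;
    annotates catalytic-triad status, secretion and membrane flags, and the
    exon structure of placed domains; computes single-cell trypsin
    co-expression statistics; dates domains and trypsin-domain associations on
    a species tree by last-common-ancestor phylostratigraphy; screens gene
    trees for taxon-representation clades, same-scaffold sister pairs and
    monophyly; and generates synthetic inputs with planted ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
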