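Package: v1rCladeEvo
Title: Gene Birth-and-Death Analysis of Vomeronasal Type-1 Receptor
    Repertoires Across Mus Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the evolution of the vomeronasal
    type-1 receptor (V1R) gene family across closely related Mus species
    from transcriptome-derived coding sequences. Implements receptor
    mining (open reading frame extraction under a receptor gene model,
    best-hit annotation against a reference repertoire, containment
    deduplication and a group-identity filter), orthogroup delimitation
    on a gene tree by species-overlap reconciliation with the reference
    annotation grammar, classification of same-annotation transcripts as
    transcript variants versus gene duplicates, a counting-based branch
    dN/dS screen with false-discovery-rate correction and per-clade
    aggregation, repertoire turnover summaries including gene-loss calls,
    and membrane-topology-aware amino acid site classification. A codon
    level birth-and-death simulator generates multi-species repertoires
    with known histories so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    phangorn,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
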