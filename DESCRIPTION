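Package: teloquest
Title: Telomere Motif Inference and Telomerase RNA Discovery in Beetle Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers species-specific telomeric repeat motifs from genome
    assembly termini or raw reads, discovers telomerase RNA (TR) candidate
    loci by template-guided scanning with cross-species homology filtering,
    checks conserved structural anchors (template boundary hairpin,
    pseudoknot) and type-3 snRNA promoter architecture, screens assemblies
    for TERT-like coding sequence by six-frame translated search, and maps
    putative telomerase-loss events onto a species tree by Dollo parsimony.
    Ships a synthetic multi-species genome simulator with planted ground
    truth for end-to-end validation of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    ape,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    jsonlite
Config/testthat/edition: 3
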