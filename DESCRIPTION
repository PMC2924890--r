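Package: concord
Title: Cross-Omics Differential Expression and Fold-Change Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares a two-channel common-reference microarray transcriptome
    with an iTRAQ 4-plex proteome in species without a sequenced genome.
    Provides Generalized Procrustes Analysis normalization and one-class SAM
    permutation q-values for transcript selection, peptide-spectrum-match
    filtering with protein ratio aggregation, error factors and reversed-decoy
    FDR for the proteome, six-frame translated Smith-Waterman matching of
    differentially expressed ESTs to differentially expressed proteins with
    Karlin-Altschul E-values, and directional fold-change concordance
    statistics over the matched mRNA-protein pairs. Includes a synthetic-data
    generator with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
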