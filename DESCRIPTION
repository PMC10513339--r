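Package: pirnakit
Title: Small RNA Ping-Pong Signatures and Transposon Derepression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for PIWI-interacting RNA (piRNA) sequencing analysis in the
    silkworm model: 3'-adapter removal for 4N-randomized adapter libraries,
    collapsing to unique inserts, mapping to a transposon/gene/miRNA reference
    catalog, reads-per-million normalization against transposon-mapped or
    top-10-miRNA denominators, ping-pong signature quantification (10-nt 5'-5'
    overlap), 1U/10A strand-bias tables, piRNA-producer classification with
    three-set Venn decomposition, TPM-based MA transforms and transposon
    derepression calls, permutation-based differential expression with BH FDR,
    Z-score clustering, tissue-specificity rules, and piRNA-guided slicer target
    scanning under the 2-18 nt pairing rule. Includes a synthetic-data generator
    with ground-truth tables so every stage is testable without external
    sequencing libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    BiocGenerics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
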