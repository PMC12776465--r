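Package: tmdslip
Title: Discovery of Transmembrane-Domain-Coupled Ribosomal Frameshift Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to discover "TMD-slip" motifs in coding transcriptomes:
    heptanucleotide slip sites scored by the free-energy penalty of tRNA
    re-pairing in the -1 reading frame (dG_FS), translocon-engaged
    transmembrane segments refined with a biological hydrophobicity scale
    (dG_app), and pairing of the two at translation-coupled codon distances.
    Includes frameshift-product prediction and proteogenomic peptide database
    construction, randomization null models and exact tests for motif
    positioning and nonsense-mediated-decay association, and a synthetic
    transcriptome generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
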