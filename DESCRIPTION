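Package: idrscope
Title: Intrinsic Disorder Annotation and Evolution in Spliceosomal Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates intrinsically disordered regions (IDRs) in protein
    sequences from per-residue disorder scores, classifies them by
    compositional bias (RS-like, poly-P/Q, G-rich, charged, noncharged)
    and by embedded secondary structure, and quantifies their association
    with post-translational modifications and cancer-associated mutations
    (Fisher exact enrichment, paired Wilcoxon density tests, permutation
    tests for PTM-flanking mutations).  A phylogenetic stage maps disorder
    calls onto ortholog alignments and scores disorder-to-order transitions
    by Fitch parsimony, including per-clade net gain of disorder.  A fully
    seeded synthetic-data generator produces ground-truth-labelled
    proteomes, PTM/mutation tables and ortholog families so every stage can
    be benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
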