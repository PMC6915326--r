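Package: cuic
Title: Analysis of the CUIC 5' UTR Motif in Ribosomal-Protein mRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the pyrimidine-rich cis-element upstream of the
    initiation codon (CUIC, consensus YYYYTTYC) in 5' UTRs of ribosomal-protein
    mRNAs and its structural and regulatory context. Provides IUPAC-degenerate
    motif scanning and positional classification of transcripts, TOP-like
    isoform calls from 5'-end observations, motif-anchored double-stranded
    fraction profiles from dot-bracket secondary structures (with a
    maximum-base-pairing stand-in folder), CLIP-cluster binding-specificity
    scores for RNA-binding proteins, a protein-rRNA interface-index computed
    from complex structures via solvent-accessible surface area or atomic
    contacts, the associated abundance-bias statistics (two-sample
    Kolmogorov-Smirnov, rank-sum, Fisher's exact depletion, stage ratios, FRAP
    recovery), and seeded generators of synthetic benchmark data with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
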