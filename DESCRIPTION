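Package: pptract
Title: Strand Asymmetry and Mutation-Selection Analysis of Polypyrimidine
    Tracts in Short Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study base-composition evolution of the polypyrimidine
    tract (3PT) of short spliceosomal introns against a putatively neutral
    5' reference region (5LR).  Extracts oriented intron alignments from a
    reference genome (FASTA + GFF3) plus per-individual consensus genomes,
    cuts the 5LR / 3PT / 3'-junction windows with coding-sequence and
    missing-data filters, computes k-mer strand-asymmetry scores with
    chi-square and equivalence tests, quantifies per-motif scaled selection
    coefficients as 3PT-vs-5LR log-odds with intron bootstrap confidence
    intervals, estimates the strength of GC-biased gene conversion from
    site-frequency spectra by maximum likelihood, fits a context-dependent
    mutation-selection model (monomer selection plus an AG-dimer term)
    per position by maximum likelihood with likelihood-ratio model
    comparison, and provides an exact Gillespie simulator of a circular
    sequence evolving under the fitted model.  A synthetic-data module
    generates annotated genomes, region sets and spectra with known ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
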