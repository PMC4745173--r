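Package: waveslope
Title: Translation-Invariant Wavelet Spectral Slopes for DNA Regularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the regularity of DNA sequences by a log-spectral slope
    computed from a 2-D scale-mixing Haar wavelet transform of cumulative
    unit-vector indicator matrices. Nucleotide-to-number assignments fall into
    three equivalence classes; stacking one encoding from each class makes the
    slope invariant to the assignment. Provides global and sliding-window
    ("cumulative evolutionary") slopes, exon/intron region labeling and pooled
    section statistics, bootstrap and permutation significance, Youden-index
    threshold classification metrics, synthetic sequence generators, FASTA and
    BED/GFF3 input, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
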