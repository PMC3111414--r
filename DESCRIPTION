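Package: dielscan
Title: Model-Based Detection of Diurnal and Circadian Transcriptome Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing diurnal and circadian time-course
    transcriptomes. Detects rhythmic genes by Pearson correlation of each
    expression series against a library of phased model waveforms, assigns a
    phase of peak expression, and estimates false discovery rates by
    permutation. Scores 3-8-mer promoter words for phase-specific
    overrepresentation as 24-bin Z-score profiles with a consecutive-bin
    significance rule, and compares enrichment profiles across species.
    Predicts orthologs from reciprocal best hit tables and quantifies
    cross-species phase concordance on the 24-hour circle. Includes a
    synthetic-data generator with planted rhythms, motifs and ortholog
    trios for ground-truth validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
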