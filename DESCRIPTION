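Package: annotweave
Title: Evidence-Based Reference Annotation Updating from Assembled Transcripts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Updates a draft-genome annotation using assembled transcript
    evidence. Each assembled (e.g. StringTie) transcript is classified
    against the reference annotation by intron-chain comparison and exonic
    overlap; novel isoforms are added to existing genes, neighboring genes
    joined by transcription-unit evidence are merged via transitive closure,
    and intergenic transcript clusters become novel genes. The package also
    computes the downstream accounting used to describe such an update:
    assembly summary statistics, merge-size distributions, gene-level
    reconciliation of transcript-mode BUSCO results, and threshold-based
    differential-expression summaries (fold-change bins, multi-timepoint
    overlap sets, top tables, and ranked-list exports for enrichment).
    A deterministic fixture generator produces reference/evidence GTF pairs,
    BUSCO tables, and differential-expression tables with ground-truth logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
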