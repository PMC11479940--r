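Package: polySVA
Title: Epigenetic Profiling of Polymorphic SVA Retrotransposon Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the epigenetic silencing of polymorphic SVA
    (SINE-VNTR-Alu) retrotransposon insertions in long-read and chromatin
    profiling data. Implements filtering of non-reference insertion calls,
    construction of insertion-augmented genomes with exact bidirectional
    coordinate maps and annotation liftover, spike-in-scaled scale-regions
    signal profiling over repeat boundaries, region-wise aggregation of
    nanopore per-read CpG methylation calls, noise-tolerant tandem hexamer
    copy-number estimation by wraparound dynamic programming, TPM and
    median-of-ratios expression normalization with intron-retention and
    cis-linkage summaries, and a seeded synthetic-data generator with a
    planted truth set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
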