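Package: emburst
Title: Tracking an LTR Retrotransposon Burst from Enzymatic Methyl-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to follow the genomic proliferation of an active LTR
    retrotransposon (modelled on the Arabidopsis Ty1/Copia element EVADE)
    from enzymatic methyl-sequencing (EM-seq) libraries. The package calls
    non-reference insertions from discordant read-mate clusters, infers
    target-site duplications, insertion strand and LTR-of-origin from
    soft-clipped boundary reads, estimates element copy number from the
    coverage ratio over the reference copy and from qPCR delta-delta-Ct
    tables, quantifies weighted DNA methylation in CG/CHG/CHH contexts
    globally and per LTR of each new insertion, and classifies the
    pre-insertion methylation state of polymorphic landing sites. A
    seeded simulator generates miniature genomes with planted insertions,
    converted paired-end reads and truth-derived alignments so the whole
    pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
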