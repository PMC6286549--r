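Package: winmeth
Title: Window-Based Differential Methylation from MeDIP-seq and MRE-seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative differential-methylation analysis for paired
    MeDIP-seq (methylated signal) and MRE-seq (unmethylated signal) libraries.
    Tiles a genome into fixed-size windows (500 bp by default), applies a
    per-window conditional exact test between two conditions on
    library-size-normalized MeDIP/MRE counts, combines replicate-level
    comparisons with Fisher's combined probability test, adjusts with the
    Benjamini-Hochberg procedure, and calls differentially methylated regions
    (DMRs) at q-value cutoffs. Includes DMR annotation against gene models and
    Ensembl-style regulatory features (promoter/exon/intron/intergenic
    classification, nearest gene, regulatory overlap), a regulatory-region
    chi-square enrichment test, an intergenic-constrained randomization test of
    DMR overlap with differentially expressed genes, trapezoidal
    area-under-the-curve summaries for glucose/insulin tolerance series, and a
    seeded synthetic-data generator that emulates every pipeline input.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
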