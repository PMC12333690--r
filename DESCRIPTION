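Package: isomod
Title: Isoform-Level m6A Modification and Poly(A) Tail Analysis from Direct RNA Sequencing Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of isoform-resolved N6-methyladenosine (m6A)
    maps and poly(A) tail lengths derived from nanopore direct RNA sequencing
    summaries. Provides transcript-to-genome coordinate services on a GTF
    annotation, consensus calling of high-confidence m6A sites from per-sample
    site tables, classification of commonly versus region-specifically
    modified genes and isoforms with expression-aware adjustment,
    length-normalised hypermodification scoring, differential-modification
    testing between isoforms sharing a genomic site and between tissues,
    per-isoform poly(A) tail summaries and differential poly(A) length tests,
    a self-contained statistical kernel (pooled two-proportion z, BH FDR,
    Mann-Whitney U with exact small-sample enumeration, Spearman,
    hypergeometric overlap, windowed genomic overlap), and a deterministic
    synthetic-data generator with recorded planted truth so every stage is
    verifiable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
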