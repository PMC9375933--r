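Package: lectinscan
Title: Genome-Wide Lectin Gene Family Annotation, QTL Co-Localization and
    Expansion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide analysis of plant lectin gene families:
    domain-based family assignment against the twelve canonical plant lectin
    domain signatures, merolectin/hololectin/chimerolectin architecture
    classification, secretion-class tabulation and protein pI/Mw computation;
    merging of overlapping quantitative trait loci (QTL) into non-redundant
    trait-grouped regions and gene co-localization by physical position; a
    Wald overrepresentation test for lectin density in QTL regions with an
    exact hypergeometric cross-check and Bonferroni-style significance
    flagging; duplicate-pair classification (tandem, proximal, dispersed,
    transposed, whole-genome duplication) with Nei-Gojobori (1986) Ka/Ks and
    a Ks <= 1 retention filter; strand-aware promoter extraction with IUPAC
    cis-regulatory element scanning and perfect simple-sequence-repeat (SSR)
    detection; and a deterministic synthetic-genome generator with a
    planted-truth manifest so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
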