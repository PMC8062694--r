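Package: darkpep
Title: Proteogenomic Discovery of Noncoding-Gene-Encoded Peptides and Dark
    Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable proteogenomics pipeline for discovering
    peptides translated from predicted noncoding genes (pseudogenes,
    lncRNAs, retroelements and other non-canonical regions). Builds
    three-frame-translation search databases with reversed-sequence
    decoys, estimates class-specific false-discovery rates for novel
    peptides, maps accepted peptides back to genomic coordinates and
    groups them into novel coding loci, quantifies loci across
    tumor/normal designs (label-free and isobaric), classifies tissue
    specificity, screens 9-mers for MHC class I presentation by
    percentile rank against random natural peptides, and nominates
    "dark antigen" candidates. Includes seeded synthetic-data
    generators that emulate the statistical structure of large
    cancer-proteomics studies so the whole pipeline can be exercised
    and validated end-to-end at desk scale.
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
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
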