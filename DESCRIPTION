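Package: plasmaCNA
Title: Genome-Wide Instability Scoring and Copy-Number Biomarkers from
    Plasma Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for circulating cell-free DNA (cfDNA)
    copy-number biomarkers from low-depth whole-genome sequencing.
    Tiles the autosomal genome into fixed-size bins, counts
    high-mapping-quality reads per bin, removes GC bias by LOESS
    smoothing, converts counts to normalized percentages, and scores
    each sample against a healthy reference panel with per-bin
    Z-scores.  Genomic instability is summarized by the I-score (sum
    of absolute Z-scores exceeding a threshold) and the S-score (sum
    of all squared Z-scores).  Also provides droplet digital PCR
    Poisson copy-number quantification for the VEGFA-to-EIF2C1 ratio
    with a control-derived amplification cutoff, downstream biomarker
    survival statistics (disease control rate, median and quartile
    dichotomization, Kaplan-Meier, log-rank, proportional hazards),
    and a synthetic-cohort generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    Biostrings,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
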