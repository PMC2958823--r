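Package: nucflow
Title: Single-Cell Quantification of Nucleocytoplasmic Protein Dynamics
    from Time-Lapse Fluorescence Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify protein levels and nuclear translocation in
    individual cells from multi-channel time-lapse fluorescence microscopy.
    Provides flat-field and background correction, seeded segmentation of
    cells and nuclei from a reference channel, nearest-centroid tracking
    with automatic division detection, population variability statistics
    (coefficient of variation, 90:10 percentile ratio), per-cell response
    metrics of drug-induced nuclear accumulation, and a lag cross-correlation
    analysis of the co-dynamics of two tagged proteins with its decorrelation
    time. A synthetic movie generator with full ground-truth annotation
    supports validation of every stage, and a small in-silico module models
    artificial-exon gene tagging (cassette reading frames, splicing, RT-PCR
    and 3'RACE amplicon prediction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dynamics-stats.R'
    'tracking.R'
    'segmentation.R'
    'synthetic-params.R'
    'synthetic-movie.R'
    'benchmark.R'
    'movie-io.R'
    'nucflow-package.R'
    'tag-design.R'
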